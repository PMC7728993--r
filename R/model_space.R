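## Model-space enumeration: every directed inter-regional connection takes
## one of {absent, present, present+modulated}; each region does or does not
## receive the driving input. Self-connections are always present and never
## modulated. Enumeration order is lexicographic over the code columns
## (leftmost most significant), so model indices are reproducible.

.edgeTable <- function(l) {
  ## candidate directed edges in fixed order: source-major, matching
  ## column-major traversal of the A matrix
  src <- rep(seq_len(l), each = l)
  tgt <- rep(seq_len(l), times = l)
  keep <- src != tgt
  cbind(target = tgt[keep], source = src[keep])
}

.mixedRadix <- function(n, radices) {
  ## decode 0..(prod-1) into digits, leftmost most significant
  k <- length(radices)
  place <- rev(cumprod(rev(c(radices[-1], 1))))
  idx <- seq_len(n) - 1L
  codes <- matrix(0L, n, k)
  for (col in seq_len(k))
    codes[, col] <- as.integer((idx %/% place[col]) %% radices[col])
  codes
}

.makeSpace <- function(regionNames, nInputs, edges, codes, rule,
                       variant, states, familyLabels = character(0)) {
  new("ModelSpace", regionNames = regionNames, nInputs = nInputs,
      edges = edges, codes = codes, rule = rule,
      variant = rep_len(variant, nrow(codes)), states = states,
      familyLabels = familyLabels)
}

#' Enumerate the full model space over l regions
#'
#' Every directed inter-regional connection independently takes one of the
#' three states absent / present / present-with-modulation (for the single
#' modulatory input), and each region independently does or does not
#' receive the driving input. Self-connections are always present and never
#' modulated. The count is \eqn{3^{l(l-1)} \cdot 2^l}: 5,832 models for
#' three regions.
#'
#' @param l number of regions (>= 1).
#' @param m number of modulatory inputs; only \code{m = 1} (one
#'   experimental condition) is supported, matching the construction the
#'   count formula is stated for.
#' @param variant,states passed through to the materialised
#'   [ModelSpec-class]s.
#' @param regionNames optional labels.
#' @return A [ModelSpace-class]; materialise single models with
#'   [modelAt()].
#' @examples
#' nModels(enumerateFull(2))  # 36
#' @export
enumerateFull <- function(l, m = 1L, variant = "bilinear", states = "one",
                          regionNames = NULL) {
  if (l < 1L) stop("invalid parameter: l must be >= 1")
  if (m != 1L) stop("only one modulatory input (m = 1) is supported")
  if (is.null(regionNames)) regionNames <- paste0("R", seq_len(l))
  edges <- .edgeTable(l)
  nE <- nrow(edges)
  codes <- .mixedRadix(3^nE * 2^l, c(rep(3L, nE), rep(2L, l)))
  .makeSpace(regionNames, 1L, edges, codes,
             rule = sprintf("full enumeration, %d regions", l),
             variant = variant, states = states)
}

.reachableFrom <- function(present, edges, l, start) {
  ## present: logical over edge rows
  reach <- rep(FALSE, l)
  reach[start] <- TRUE
  repeat {
    new <- present & reach[edges[, "source"]] & !reach[edges[, "target"]]
    if (!any(new)) break
    reach[edges[new, "target"]] <- TRUE
  }
  reach
}

#' Enumerate the input-constrained model space
#'
#' The driving input is fixed to a single designated region; each directed
#' inter-regional connection takes one of absent / present /
#' present-with-modulation, and a model is retained only if every other
#' region is reachable from the input region through present connections
#' (the input must be able to propagate to the whole network). For three
#' regions this yields 540 models.
#'
#' @param l number of regions.
#' @param inputRegion index (or name) of the region receiving the driving
#'   input.
#' @param variant,states,regionNames as in [enumerateFull()].
#' @return A [ModelSpace-class].
#' @examples
#' nModels(enumerateInputConstrained(2, 1))  # 6
#' @export
enumerateInputConstrained <- function(l, inputRegion = 1L,
                                      variant = "bilinear", states = "one",
                                      regionNames = NULL) {
  if (l < 1L) stop("invalid parameter: l must be >= 1")
  if (is.null(regionNames)) regionNames <- paste0("R", seq_len(l))
  if (is.character(inputRegion))
    inputRegion <- match(inputRegion, regionNames)
  if (is.na(inputRegion) || inputRegion < 1L || inputRegion > l)
    stop("invalid input region")
  edges <- .edgeTable(l)
  nE <- nrow(edges)
  codes <- .mixedRadix(3^nE, rep(3L, nE))
  keep <- vapply(seq_len(nrow(codes)), function(r) {
    all(.reachableFrom(codes[r, ] > 0L, edges, l, inputRegion))
  }, TRUE)
  codes <- codes[keep, , drop = FALSE]
  input <- matrix(0L, nrow(codes), l)
  input[, inputRegion] <- 1L
  .makeSpace(regionNames, 1L, edges, cbind(codes, input),
             rule = sprintf("input fixed to region %d, reachability-filtered",
                            inputRegion),
             variant = variant, states = states)
}

#' Materialise one model of a ModelSpace
#'
#' @param space a [ModelSpace-class].
#' @param i model index (1-based, in enumeration order).
#' @return A [ModelSpec-class].
#' @export
modelAt <- function(space, i) {
  stopifnot(i >= 1L, i <= nrow(space@codes))
  l <- length(space@regionNames)
  nE <- nrow(space@edges)
  code <- space@codes[i, ]
  Amask <- diag(l) == 1
  Bmask <- matrix(FALSE, l, l)
  es <- code[seq_len(nE)]
  on <- es > 0L
  Amask[space@edges[on, , drop = FALSE]] <- TRUE
  Bmask[space@edges[es == 2L, , drop = FALSE]] <- TRUE
  Cmask <- matrix(code[nE + seq_len(l)] > 0L, l, 1)
  modelSpec(space@regionNames, Amask, Bmasks = list(Bmask), Cmask,
            variant = space@variant[i], states = space@states)
}

#' Combine two model spaces over the same regions
#'
#' Concatenates two spaces (for instance the same structural space under
#' the bilinear and the Wilson-Cowan equation) into one, keeping each
#' model's variant. Models must remain pairwise distinct across the
#' combination.
#'
#' @param x,y [ModelSpace-class] objects sharing regions and inputs.
#' @return A [ModelSpace-class] with \code{nModels(x) + nModels(y)} models.
#' @export
combineSpaces <- function(x, y) {
  stopifnot(identical(x@regionNames, y@regionNames),
            identical(x@states, y@states))
  key <- c(paste(apply(x@codes, 1, paste, collapse = ""), x@variant),
           paste(apply(y@codes, 1, paste, collapse = ""), y@variant))
  if (anyDuplicated(key))
    stop("combined space would contain duplicate models")
  .makeSpace(x@regionNames, x@nInputs, x@edges, rbind(x@codes, y@codes),
             rule = paste(x@rule, "+", y@rule),
             variant = c(x@variant, y@variant), states = x@states)
}

#' Partition a model space into families
#'
#' Applies a total predicate to every model and stores the induced family
#' labels in the space. The canonical use is the two-family split of a
#' duplicated structure space into bilinear and Wilson-Cowan models.
#'
#' @param space a [ModelSpace-class].
#' @param predicate a function taking a [ModelSpec-class] and returning a
#'   family label, or a ready-made vector of labels (one per model).
#' @return the space with \code{familyLabels} filled in (retrieve with
#'   [familyLabels()]).
#' @export
partitionFamilies <- function(space, predicate) {
  labels <- if (is.function(predicate)) {
    vapply(seq_len(nModels(space)),
           function(i) as.character(predicate(modelAt(space, i))), "")
  } else {
    if (length(predicate) != nModels(space))
      stop("need one family label per model")
    as.character(predicate)
  }
  space@familyLabels <- labels
  validObject(space)
  space
}

#' @rdname partitionFamilies
#' @param space a [ModelSpace-class].
#' @export
familyLabels <- function(space) space@familyLabels
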
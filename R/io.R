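## File formats. All series files are TSV, row per sample, seconds
## everywhere; region order is the header order. A leading comment line
## carries the sampling step ("# TR=2" or "# dt=0.125").

.headerValue <- function(lines, key) {
  pat <- sprintf("^#\\s*%s\\s*=\\s*([0-9.eE+-]+)\\s*$", key)
  hit <- grep(pat, lines)
  if (!length(hit)) return(NULL)
  as.numeric(sub(pat, "\\1", lines[hit[1]]))
}

.parseNumericTable <- function(lines, path, firstDataLine) {
  rows <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L)
    stop(sprintf("format error in %s: ragged row at line %d (%d fields, expected %d)",
                 path, firstDataLine + which(widths != widths[1])[1] - 1L,
                 widths[widths != widths[1]][1], widths[1]))
  mat <- matrix(NA_real_, length(rows), widths[1])
  for (r in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[r]]))
    bad <- which(is.na(vals) & !(rows[[r]] %in% c("NA")))
    if (length(bad))
      stop(sprintf("format error in %s: non-numeric cell at line %d, column %d ('%s')",
                   path, firstDataLine + r - 1L, bad[1], rows[[r]][bad[1]]))
    mat[r, ] <- vals
  }
  mat
}

#' Read and write BOLD series as TSV
#'
#' The on-disk form is a tab-separated table with a leading comment line
#' \code{# TR=<seconds>}, a header row of region names, and one row per
#' sample (percent signal change). Reading fails loudly on a missing TR,
#' ragged rows or non-numeric cells, naming the offending line; writing
#' uses full precision so that a write/read cycle is bit-identical.
#'
#' @param path file path.
#' @return [readBoldTsv()]: a [BOLDSeries-class].
#' @export
readBoldTsv <- function(path) {
  lines <- readLines(path)
  TR <- .headerValue(lines, "TR")
  if (is.null(TR))
    stop(sprintf("format error in %s: missing '# TR=' header line", path))
  body <- grep("^#", lines, invert = TRUE, value = FALSE)
  if (length(body) < 2L)
    stop(sprintf("format error in %s: need a header row and data", path))
  header <- strsplit(lines[body[1]], "\t", fixed = TRUE)[[1]]
  dataLines <- lines[body[-1]]
  mat <- .parseNumericTable(dataLines, path, body[2])
  if (ncol(mat) != length(header))
    stop(sprintf("format error in %s: %d header fields but %d data columns",
                 path, length(header), ncol(mat)))
  if (anyNA(mat))
    stop(sprintf("format error in %s: missing values are not allowed", path))
  boldSeries(mat, TR = TR, regionNames = header)
}

#' @rdname readBoldTsv
#' @param bold a [BOLDSeries-class].
#' @export
writeBoldTsv <- function(bold, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# TR=%.17g", repetitionTime(bold)), con)
  writeLines(paste(regionNames(bold), collapse = "\t"), con)
  y <- boldMatrix(bold)
  writeLines(apply(y, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Compile an event list to an input timeline
#'
#' Events are (name, onset, duration) triples in seconds; each distinct
#' name becomes one input row of 0/1 boxcars (or the given amplitude) on
#' the microtime grid. Overlapping events of one input are merged with a
#' warning; negative onsets are an error. Compilation is idempotent:
#' compiling the result of [timelineToEvents()] reproduces the sampled
#' array.
#'
#' @param events data.frame with columns \code{name}, \code{onset},
#'   \code{duration} and optionally \code{amplitude}.
#' @param dt microtime step (s).
#' @param duration total timeline length (s).
#' @param inputNames optional ordering of the inputs (default: order of
#'   first appearance).
#' @return An [InputTimeline-class].
#' @export
eventsToTimeline <- function(events, dt, duration, inputNames = NULL) {
  if (any(events$onset < 0)) stop("negative onsets are not allowed")
  if (is.null(events$amplitude)) events$amplitude <- rep(1, nrow(events))
  if (is.null(inputNames)) inputNames <- unique(as.character(events$name))
  n <- as.integer(round(duration / dt))
  u <- matrix(0, length(inputNames), n,
              dimnames = list(inputNames, NULL))
  for (nm in inputNames) {
    ev <- events[events$name == nm, , drop = FALSE]
    covered <- rep(FALSE, n)
    for (r in seq_len(nrow(ev))) {
      from <- as.integer(floor(ev$onset[r] / dt + 1e-9)) + 1L
      len <- as.integer(round(ev$duration[r] / dt))
      idx <- seq.int(from, length.out = len)
      idx <- idx[idx >= 1L & idx <= n]
      if (any(covered[idx]))
        warning(sprintf("overlapping events for input '%s' merged", nm))
      covered[idx] <- TRUE
      u[nm, idx] <- ev$amplitude[r]
    }
  }
  inputTimeline(u, dt = dt, inputNames = inputNames)
}

#' Recover an event list from a timeline
#'
#' Inverse of [eventsToTimeline()] for piecewise-constant inputs: each
#' maximal run of a nonzero constant value becomes one event.
#'
#' @param timeline an [InputTimeline-class].
#' @return data.frame with columns \code{name}, \code{onset},
#'   \code{duration}, \code{amplitude}.
#' @export
timelineToEvents <- function(timeline) {
  u <- inputMatrix(timeline)
  dt <- microtimeStep(timeline)
  out <- list()
  for (i in seq_len(nrow(u))) {
    r <- rle(u[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nz <- which(r$values != 0)
    for (k in nz)
      out[[length(out) + 1L]] <- data.frame(
        name = timeline@inputNames[i],
        onset = (starts[k] - 1L) * dt,
        duration = r$lengths[k] * dt,
        amplitude = r$values[k], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(name = character(), onset = numeric(),
                      duration = numeric(), amplitude = numeric()))
  do.call(rbind, out)
}

#' Read experimental inputs
#'
#' Accepts either the sampled form (TSV with a \code{# dt=} comment line
#' and a header of input names, one row per microtime step) or an event
#' list (TSV with columns name, onset, duration, optional amplitude),
#' which is compiled to the grid via [eventsToTimeline()] and then needs
#' \code{dt} and \code{duration}.
#'
#' @param path file path.
#' @param dt,duration required for the event-list form.
#' @return An [InputTimeline-class].
#' @export
readInputs <- function(path, dt = NULL, duration = NULL) {
  lines <- readLines(path)
  dtHeader <- .headerValue(lines, "dt")
  body <- grep("^#", lines, invert = TRUE)
  header <- strsplit(lines[body[1]], "\t", fixed = TRUE)[[1]]
  if (!is.null(dtHeader)) {
    mat <- .parseNumericTable(lines[body[-1]], path, body[2])
    if (ncol(mat) != length(header))
      stop(sprintf("format error in %s: header/data column mismatch", path))
    return(inputTimeline(t(mat), dt = dtHeader, inputNames = header))
  }
  if (!all(c("name", "onset", "duration") %in% header))
    stop(sprintf("format error in %s: need '# dt=' header or columns name/onset/duration",
                 path))
  ev <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  if (is.null(dt) || is.null(duration))
    stop("event-list inputs need dt and duration")
  eventsToTimeline(ev, dt = dt, duration = duration)
}

#' @rdname readInputs
#' @param timeline an [InputTimeline-class].
#' @export
writeInputsTsv <- function(timeline, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%.17g", microtimeStep(timeline)), con)
  writeLines(paste(timeline@inputNames, collapse = "\t"), con)
  u <- t(inputMatrix(timeline))
  writeLines(apply(u, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read and write evidence tables
#'
#' Subjects-by-models free-energy tables as TSV: header row of model
#' labels, one row per subject.
#'
#' @param path file path.
#' @export
readEvidenceTsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  as.matrix(tab)
}

#' @rdname readEvidenceTsv
#' @param F evidence matrix with model labels as column names.
#' @export
writeEvidenceTsv <- function(F, path) {
  write.table(F, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a ModelSpec as JSON
#'
#' Structured-text serialisation of a [ModelSpec-class]: region names,
#' 0/1 masks, variant and states. Unknown fields are rejected.
#'
#' @param path file path.
#' @export
readModelSpecJson <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  allowed <- c("regionNames", "Amask", "Bmasks", "Cmask", "variant", "states")
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown model-spec fields: ", paste(extra, collapse = ", "))
  l <- length(x$regionNames)
  Bm <- x$Bmasks
  if (is.array(Bm) && length(dim(Bm)) == 3L)
    Bm <- lapply(seq_len(dim(Bm)[1]), function(j) matrix(Bm[j, , ] > 0, l, l))
  else if (is.matrix(Bm)) Bm <- list(Bm > 0)
  else Bm <- lapply(Bm, function(b) matrix(unlist(b) > 0, l, l))
  modelSpec(x$regionNames, matrix(unlist(x$Amask) > 0, l, l), Bm,
            matrix(unlist(x$Cmask) > 0, l),
            variant = x$variant, states = x$states)
}

#' @rdname readModelSpecJson
#' @param spec a [ModelSpec-class].
#' @export
writeModelSpecJson <- function(spec, path) {
  jsonlite::write_json(list(
    regionNames = regionNames(spec),
    Amask = connectionMask(spec) * 1L,
    Bmasks = lapply(modulationMasks(spec), function(b) b * 1L),
    Cmask = drivingMask(spec) * 1L,
    variant = variant(spec), states = spec@states),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
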
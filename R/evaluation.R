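## Validation harness: connection-detection ROC/AUC, SNR sweeps comparing
## neuronal variants by explained variance and flat-line counts, parameter
## recovery metrics, and model-recovery confusion matrices.

#' ROC curve for connection detection
#'
#' Sweeps a probability threshold from strict to lenient over per-edge
#' presence scores: an edge is predicted present iff its score exceeds the
#' threshold (strictly). A false positive is a predicted edge that is
#' absent in the generator; a missed generator edge is a false negative.
#' The AUC is the trapezoidal area under the (fpr, tpr) path, with the
#' (0, 0) and (1, 1) endpoints included.
#'
#' @param scores numeric vector (or runs-by-edges matrix, flattened) of
#'   presence probabilities, e.g. from [connectionScores()].
#' @param truth logical vector: is the edge present in the generator?
#'   Recycled across runs when \code{scores} is a matrix.
#' @return An [ROCResult-class].
#' @examples
#' auc(connectionROC(c(0.9, 0.8, 0.4, 0.2), c(TRUE, FALSE, TRUE, FALSE)))
#' @export
connectionROC <- function(scores, truth) {
  if (is.matrix(scores)) scores <- as.numeric(t(scores))  # run-major
  truth <- rep_len(as.logical(truth), length(scores))
  if (!any(truth) || all(truth))
    stop("undefined AUC: truth must contain both present and absent edges")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[truth] > t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!truth] > t), 0)
  a <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  new("ROCResult", thresholds = thr, tpr = tpr, fpr = fpr, auc = a)
}

.saturatedSpec <- function(spec, variant) {
  l <- nRegions(spec)
  Amask <- matrix(TRUE, l, l)
  Bmasks <- lapply(spec@Bmasks, function(b) {
    if (any(b)) matrix(TRUE, l, l) & !diag(l) else matrix(FALSE, l, l)
  })
  modelSpec(regionNames(spec), Amask, Bmasks, spec@Cmask,
            variant = variant, states = spec@states)
}

#' SNR sweep comparing neuronal variants
#'
#' Generates synthetic data from a fixed ground-truth model over a grid of
#' signal-to-noise ratios and inverts every realization under both the
#' bilinear and the Wilson-Cowan equation, recording explained variance,
#' flat-line flags, free energy and per-edge connection scores. The fitted
#' structure is the saturated one (all inter-regional connections present,
#' modulation allowed wherever the generator's input modulates anything),
#' so the same fits support both the explained-variance comparison and the
#' connection-detection ROC. Fully seeded and reproducible.
#'
#' @param spec,neuronal,hemo,inputs the generating model (typically
#'   [groundTruthNetwork()] with [standardInputs()]).
#' @param snrGrid positive SNR values to sweep.
#' @param variants neuronal equations to fit.
#' @param nReal realizations per SNR.
#' @param seed integer master seed; each SNR level derives its own.
#' @param TR repetition time (s).
#' @param invertOpts options forwarded to [invertDCM()].
#' @return list with \code{summary} (data.frame: snr, variant, meanEV,
#'   seEV, flatlines, n) and \code{cells} (per-fit records including
#'   connection scores).
#' @export
snrSweep <- function(spec, neuronal, hemo = hemodynamicParams(), inputs,
                     snrGrid, variants = c("bilinear", "wilson_cowan"),
                     nReal = 5L, seed = 1L, TR = 2, invertOpts = list()) {
  stopifnot(all(snrGrid > 0))
  cells <- list()
  for (si in seq_along(snrGrid)) {
    snr <- snrGrid[si]
    ds <- simulateDataset(spec, neuronal, hemo, inputs, snr = snr,
                          nReal = nReal, seed = as.integer(seed + 97L * si),
                          TR = TR)
    for (r in seq_len(nReal)) {
      for (v in variants) {
        fitSpec <- .saturatedSpec(spec, v)
        post <- tryCatch(
          invertDCM(ds@noisy[[r]], inputs, fitSpec, opts = invertOpts),
          error = function(e) NULL)
        cells[[length(cells) + 1L]] <- list(
          snr = snr, realization = r, variant = v,
          ok = !is.null(post),
          ev = if (is.null(post)) NA_real_ else explainedVarianceOf(post),
          flatline = if (is.null(post)) NA else isFlatline(post),
          F = if (is.null(post)) NA_real_ else freeEnergy(post),
          scores = if (is.null(post)) NULL else connectionScores(post))
      }
    }
  }
  df <- do.call(rbind, lapply(cells, function(x)
    data.frame(snr = x$snr, realization = x$realization, variant = x$variant,
               ok = x$ok, ev = x$ev, flatline = x$flatline, F = x$F)))
  agg <- do.call(rbind, lapply(split(df, list(df$snr, df$variant)), function(d) {
    evs <- d$ev[d$ok]
    data.frame(snr = d$snr[1], variant = d$variant[1],
               meanEV = mean(evs, na.rm = TRUE),
               seEV = if (length(evs) > 1) sd(evs) / sqrt(length(evs)) else NA_real_,
               flatlines = sum(d$flatline, na.rm = TRUE),
               n = sum(d$ok))
  }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$snr, agg$variant), ]
  list(summary = agg, cells = cells, table = df)
}

#' ROC/AUC per variant from a sweep
#'
#' Pools the per-edge connection scores of all realizations of one variant
#' at the selected SNR levels and scores them against the generator's edge
#' set.
#'
#' @param sweep result of [snrSweep()].
#' @param spec the generating [ModelSpec-class] (defines the true edges).
#' @param variant which fitted variant to score.
#' @param snr SNR level(s) to include (default: all).
#' @return An [ROCResult-class].
#' @export
sweepROC <- function(sweep, spec, variant, snr = NULL) {
  l <- nRegions(spec)
  truthMat <- connectionMask(spec) & !diag(l)
  lay <- .edgeTable(l)
  truth <- truthMat[lay]
  sel <- Filter(function(x) x$ok && x$variant == variant &&
                  (is.null(snr) || x$snr %in% snr), sweep$cells)
  if (!length(sel)) stop("no successful fits for this variant/snr")
  scores <- unlist(lapply(sel, function(x) {
    key <- sprintf("%d<-%d", lay[, "target"], lay[, "source"])
    x$scores[key]
  }))
  connectionROC(scores, rep(truth, length(sel)))
}

#' Parameter-recovery metrics
#'
#' Element-wise comparison of the generating coupling values with the
#' posterior means over the nonzero (mask-allowed) couplings: bias
#' (posterior mean minus truth), RMSE, and the Pearson correlation (only
#' when at least 3 couplings are compared).
#'
#' @param trueNeuronal the generating [NeuronalParams-class].
#' @param posterior a [DCMPosterior-class] fitted with a spec sharing the
#'   generator's structure.
#' @return list with \code{table} (parameter, truth, estimate, bias),
#'   \code{rmse}, \code{correlation} (NA when fewer than 3 couplings).
#' @export
recoveryMetrics <- function(trueNeuronal, posterior) {
  spec <- posterior@spec
  stopifnot(spec@states == "one")
  lay <- .paramLayout(spec)
  sel <- lay$group %in% c("A", "B", "C")
  lay <- lay[sel, , drop = FALSE]
  truth <- vapply(seq_len(nrow(lay)), function(r) {
    with(lay[r, ], switch(group,
      A = trueNeuronal@A[i, j],
      B = trueNeuronal@B[[k]][i, j],
      C = trueNeuronal@Cin[i, k]))
  }, 0)
  est <- posterior@mean[lay$name]
  tab <- data.frame(parameter = lay$name, truth = truth,
                    estimate = unname(est), bias = unname(est) - truth)
  list(table = tab,
       rmse = sqrt(mean(tab$bias^2)),
       correlation = if (nrow(tab) >= 3) cor(tab$truth, tab$estimate)
                     else NA_real_)
}

#' Model-recovery confusion matrix
#'
#' Uses each candidate model in turn as the generator, simulates seeded
#' noisy realizations, inverts every realization under every candidate,
#' and counts which model attains the highest free energy. Entry (i, j) is
#' the number of realizations generated under model i and won by model j;
#' rows sum to the realization count.
#'
#' @param specs list of K >= 2 [ModelSpec-class] candidates.
#' @param neuronals list of K generating parameter sets (one per spec).
#' @param hemo,inputs shared generative settings.
#' @param snr signal-to-noise ratio of the simulated data.
#' @param nReal realizations per generator.
#' @param seed master seed.
#' @param TR repetition time (s).
#' @param invertOpts options forwarded to [invertDCM()].
#' @return K-by-K integer matrix of selection counts.
#' @export
modelRecovery <- function(specs, neuronals, hemo = hemodynamicParams(),
                          inputs, snr, nReal = 5L, seed = 1L, TR = 2,
                          invertOpts = list()) {
  K <- length(specs)
  stopifnot(K >= 2L, length(neuronals) == K)
  conf <- matrix(0L, K, K)
  for (i in seq_len(K)) {
    ds <- simulateDataset(specs[[i]], neuronals[[i]], hemo, inputs,
                          snr = snr, nReal = nReal,
                          seed = as.integer(seed + 131L * i), TR = TR)
    for (r in seq_len(nReal)) {
      Fs <- vapply(seq_len(K), function(j) {
        post <- tryCatch(
          invertDCM(ds@noisy[[r]], inputs, specs[[j]], opts = invertOpts),
          error = function(e) NULL)
        if (is.null(post)) -Inf else freeEnergy(post)
      }, 0)
      win <- which.max(Fs)
      conf[i, win] <- conf[i, win] + 1L
    }
  }
  conf
}
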
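## Variational Bayes under the Laplace assumption (VBL): Gauss-Newton
## ascent on the free energy with Levenberg-Marquardt damping, forward
## finite-difference sensitivities, and an alternating per-region
## noise-precision (M-step) update.

## ---------------------------------------------------------------------------
## Parameter layout and priors
## ---------------------------------------------------------------------------

.paramLayout <- function(spec, sharedAlpha = FALSE) {
  l <- nRegions(spec)
  m <- spec@nInputs
  rows <- list()
  add <- function(name, group, i, j, k, mean, var)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, group = group, i = i, j = j, k = k,
      mean = mean, var = var, stringsAsFactors = FALSE)
  if (spec@states == "one") {
    for (j in seq_len(l)) for (i in seq_len(l)) if (spec@Amask[i, j]) {
      if (i == j) add(sprintf("A[%d,%d]", i, j), "A", i, j, 0L, -0.5, 1 / 256)
      else add(sprintf("A[%d,%d]", i, j), "A", i, j, 0L, 0, 1 / 16)
    }
    for (k in seq_len(m)) {
      Bm <- spec@Bmasks[[k]]
      for (j in seq_len(l)) for (i in seq_len(l)) if (Bm[i, j])
        add(sprintf("B%d[%d,%d]", k, i, j), "B", i, j, k, 0, 1 / 16)
    }
    for (k in seq_len(m)) for (i in seq_len(l)) if (spec@Cmask[i, k])
      add(sprintf("C[%d,%d]", i, k), "C", i, 0L, k, 0, 1)
    if (spec@variant == "wilson_cowan") {
      if (sharedAlpha) add("logalpha", "logalpha", 0L, 0L, 0L, log(4), 1 / 16)
      else for (i in seq_len(l))
        add(sprintf("logalpha[%d]", i), "logalpha", i, 0L, 0L, log(4), 1 / 16)
    }
  } else {
    for (j in seq_len(l)) for (i in seq_len(l))
      if (i != j && spec@Amask[i, j])
        add(sprintf("logwEE[%d,%d]", i, j), "logwEE", i, j, 0L, log(0.5), 1 / 16)
    for (grp in c("logwSE", "logwSI", "logwIE", "logwEI"))
      for (i in seq_len(l))
        add(sprintf("%s[%d]", grp, i), grp, i, 0L, 0L, log(0.5), 1 / 16)
    for (k in seq_len(m)) {
      Bm <- spec@Bmasks[[k]]
      for (j in seq_len(l)) for (i in seq_len(l))
        if (i != j && Bm[i, j])
          add(sprintf("bEE%d[%d,%d]", k, i, j), "bEE", i, j, k, 0, 1 / 16)
      for (i in seq_len(l)) if (Bm[i, i])
        add(sprintf("bIE%d[%d]", k, i), "bIE", i, 0L, k, 0, 1 / 16)
    }
    for (k in seq_len(m)) for (i in seq_len(l)) if (spec@Cmask[i, k])
      add(sprintf("C[%d,%d]", i, k), "C", i, 0L, k, 0, 1)
    if (spec@variant == "wilson_cowan") {
      for (i in seq_len(l))
        add(sprintf("logalphaE[%d]", i), "logalphaE", i, 0L, 0L, log(4), 1 / 16)
      for (i in seq_len(l))
        add(sprintf("logalphaI[%d]", i), "logalphaI", i, 0L, 0L, log(4), 1 / 16)
    }
  }
  for (i in seq_len(l)) {
    add(sprintf("logkappa[%d]", i), "logkappa", i, 0L, 0L, 0, 1 / 256)
    add(sprintf("logtauh[%d]", i), "logtauh", i, 0L, 0L, 0, 1 / 256)
  }
  do.call(rbind, rows)
}

#' Shrinkage priors for a model specification
#'
#' Builds the classical shrinkage priors on the free parameters implied by
#' the structural masks of \code{spec}. Masked-out parameters are pinned
#' (excluded from the free-parameter vector, equivalently prior variance 0).
#' Defaults on the unconstrained scale:
#' \itemize{
#'   \item off-diagonal A and B entries: N(0, 1/16); C entries: N(0, 1);
#'   \item A diagonal (self-connections): N(-0.5, 1/256);
#'   \item log sigmoid slope: N(log 4, 1/16), so the prior model starts in
#'     the small-signal regime where the Wilson-Cowan flow is equivalent to
#'     the bilinear one;
#'   \item per-region hemodynamic log-scalings on kappa and tauH:
#'     N(0, 1/256);
#'   \item per-region noise log-precision: N(6, 1/128).
#' }
#' Two-state weights are estimated on the log scale (positivity by
#' construction) with prior N(log 0.5, 1/16), modulation exponents
#' N(0, 1/16).
#'
#' @param spec a [ModelSpec-class].
#' @param sharedAlpha if \code{TRUE}, a single sigmoid slope is shared
#'   across regions (single-state Wilson-Cowan only); default one slope per
#'   region.
#' @return A [PriorSpec-class].
#' @examples
#' pr <- defaultPriors(groundTruthNetwork("wilson_cowan")$spec)
#' nFreeParams(pr)  # 21 for the three-region benchmark
#' @export
defaultPriors <- function(spec, sharedAlpha = FALSE) {
  lay <- .paramLayout(spec, sharedAlpha)
  l <- nRegions(spec)
  new("PriorSpec",
      mean = setNames(lay$mean, lay$name),
      variance = setNames(lay$var, lay$name),
      hMean = rep(6, l), hVariance = rep(1 / 128, l),
      spec = spec)
}

#' Number of free parameters (including noise log-precisions)
#' @param priors a [PriorSpec-class].
#' @export
nFreeParams <- function(priors)
  length(priors@mean) + length(priors@hMean)

## Fast theta -> integrator-argument unpacker, pre-compiled per spec --------
## (avoids rebuilding the layout and S4 objects inside the inversion loop)

.makeUnpacker <- function(lay, spec, baseHemo) {
  l <- nRegions(spec)
  m <- spec@nInputs
  one <- spec@states == "one"
  vnum <- if (spec@variant == "bilinear") 0L else 1L
  kap0 <- rep_len(baseHemo@kappa, l)
  tau0 <- rep_len(baseHemo@tauH, l)
  hemoFixed <- list(kappa = kap0, gamma = rep_len(baseHemo@gamma, l),
                    tauH = tau0, alphaG = baseHemo@alphaG, rho = baseHemo@rho,
                    V0 = baseHemo@V0, k1 = baseHemo@k1, k2 = baseHemo@k2,
                    k3 = baseHemo@k3)
  sel <- function(grp) which(lay$group == grp)
  lin <- function(rows) (lay$j[rows] - 1L) * l + lay$i[rows]
  iK <- sel("logkappa"); iT <- sel("logtauh")
  if (one) {
    iA <- sel("A"); liA <- lin(iA)
    iB <- sel("B"); liB <- lin(iB); kB <- lay$k[iB]
    iC <- sel("C"); liC <- (lay$k[iC] - 1L) * l + lay$i[iC]
    iAl <- sel("logalpha")
    function(theta) {
      A <- matrix(0, l, l); A[liA] <- theta[iA]
      B <- replicate(m, matrix(0, l, l), simplify = FALSE)
      for (r in seq_along(iB)) B[[kB[r]]][liB[r]] <- theta[iB[r]]
      C <- matrix(0, l, m); C[liC] <- theta[iC]
      alpha <- if (!length(iAl)) rep(4, l)
               else if (length(iAl) == 1L) rep(exp(theta[iAl]), l)
               else exp(theta[iAl])
      hemoFixed$kappa <- kap0 * exp(theta[iK])
      hemoFixed$tauH <- tau0 * exp(theta[iT])
      list(neuro = list(variant = vnum, states = 1L, l = l, m = m,
                        A = A, B = B, C = C, alpha = alpha),
           hemo = hemoFixed)
    }
  } else {
    iW <- sel("logwEE"); liW <- lin(iW)
    iSE <- sel("logwSE"); iSI <- sel("logwSI")
    iIE <- sel("logwIE"); iEI <- sel("logwEI")
    ibE <- sel("bEE"); libE <- lin(ibE); kbE <- lay$k[ibE]
    ibI <- sel("bIE"); kbI <- lay$k[ibI]; rbI <- lay$i[ibI]
    iC <- sel("C"); liC <- (lay$k[iC] - 1L) * l + lay$i[iC]
    iAE <- sel("logalphaE"); iAI <- sel("logalphaI")
    function(theta) {
      wEE <- matrix(0, l, l); wEE[liW] <- exp(theta[iW])
      bEE <- replicate(m, matrix(0, l, l), simplify = FALSE)
      for (r in seq_along(ibE)) bEE[[kbE[r]]][libE[r]] <- theta[ibE[r]]
      bIE <- replicate(m, numeric(l), simplify = FALSE)
      for (r in seq_along(ibI)) bIE[[kbI[r]]][rbI[r]] <- theta[ibI[r]]
      C <- matrix(0, l, m); C[liC] <- theta[iC]
      aE <- if (length(iAE)) exp(theta[iAE]) else rep(4, l)
      aI <- if (length(iAI)) exp(theta[iAI]) else rep(4, l)
      hemoFixed$kappa <- kap0 * exp(theta[iK])
      hemoFixed$tauH <- tau0 * exp(theta[iT])
      list(neuro = list(variant = vnum, states = 2L, l = l, m = m,
                        wEE = wEE, bEE = bEE, wSE = exp(theta[iSE]),
                        wSI = exp(theta[iSI]), wIE = exp(theta[iIE]),
                        wEI = exp(theta[iEI]), bIE = bIE, C = C,
                        alphaE = aE, alphaI = aI),
           hemo = hemoFixed)
    }
  }
}

## Unpack a free-parameter vector into parameter objects ---------------------

.unpackParams <- function(theta, spec, baseHemo = hemodynamicParams()) {
  lay <- .paramLayout(spec)
  l <- nRegions(spec)
  m <- spec@nInputs
  stopifnot(length(theta) == nrow(lay))
  g <- function(grp) theta[lay$group == grp]
  sub <- function(grp) lay[lay$group == grp, , drop = FALSE]
  kappa <- rep_len(baseHemo@kappa, l) * exp(g("logkappa"))
  tauH <- rep_len(baseHemo@tauH, l) * exp(g("logtauh"))
  hemo <- hemodynamicParams(kappa = kappa, gamma = rep_len(baseHemo@gamma, l),
                            tauH = tauH, alphaG = baseHemo@alphaG,
                            rho = baseHemo@rho, V0 = baseHemo@V0,
                            k1 = baseHemo@k1, k2 = baseHemo@k2,
                            k3 = baseHemo@k3)
  if (spec@states == "one") {
    A <- matrix(0, l, l); B <- replicate(m, matrix(0, l, l), simplify = FALSE)
    C <- matrix(0, l, m)
    la <- sub("A"); A[cbind(la$i, la$j)] <- g("A")
    lb <- sub("B"); vb <- g("B")
    for (r in seq_len(nrow(lb))) B[[lb$k[r]]][lb$i[r], lb$j[r]] <- vb[r]
    lc <- sub("C"); C[cbind(lc$i, lc$k)] <- g("C")
    alpha <- if (spec@variant == "wilson_cowan") {
      va <- g("logalpha")
      if (length(va) == 1L) rep(exp(va), l) else exp(va)
    } else rep(4, l)
    np <- neuronalParams(A, B, C, alpha = alpha)
  } else {
    wEE <- matrix(0, l, l)
    le <- sub("logwEE"); wEE[cbind(le$i, le$j)] <- exp(g("logwEE"))
    bEE <- replicate(m, matrix(0, l, l), simplify = FALSE)
    lbe <- sub("bEE"); vbe <- g("bEE")
    for (r in seq_len(nrow(lbe))) bEE[[lbe$k[r]]][lbe$i[r], lbe$j[r]] <- vbe[r]
    bIE <- replicate(m, numeric(l), simplify = FALSE)
    lbi <- sub("bIE"); vbi <- g("bIE")
    for (r in seq_len(nrow(lbi))) bIE[[lbi$k[r]]][lbi$i[r]] <- vbi[r]
    C <- matrix(0, l, m)
    lc <- sub("C"); C[cbind(lc$i, lc$k)] <- g("C")
    aE <- if (spec@variant == "wilson_cowan") exp(g("logalphaE")) else rep(4, l)
    aI <- if (spec@variant == "wilson_cowan") exp(g("logalphaI")) else rep(4, l)
    np <- twoStateParams(wEE, wSE = exp(g("logwSE")), wSI = exp(g("logwSI")),
                         wIE = exp(g("logwIE")), wEI = exp(g("logwEI")),
                         C = C, bEE = bEE, bIE = bIE,
                         alphaE = aE, alphaI = aI)
  }
  list(neuronal = np, hemo = hemo)
}

## ---------------------------------------------------------------------------
## Metrics
## ---------------------------------------------------------------------------

#' Percent of observed variance explained by a prediction
#'
#' \code{100 (1 - var(observed - predicted) / var(observed))}, pooled over
#' regions after removing each region's mean from both series. Can be
#' negative when the prediction is worse than the observed mean.
#'
#' @param observed,predicted [BOLDSeries-class] objects (or plain matrices)
#'   of the same shape.
#' @return explained variance in percent.
#' @export
explainedVariance <- function(observed, predicted) {
  yo <- if (is(observed, "BOLDSeries")) boldMatrix(observed) else as.matrix(observed)
  yp <- if (is(predicted, "BOLDSeries")) boldMatrix(predicted) else as.matrix(predicted)
  if (!identical(dim(yo), dim(yp))) stop("shape error: series must align")
  yo <- scale(yo, scale = FALSE)
  yp <- scale(yp, scale = FALSE)
  sso <- sum(yo^2)
  if (sso == 0) stop("undefined metric: observed series has zero variance")
  100 * (1 - sum((yo - yp)^2) / sso)
}

#' Flat-line diagnosis
#'
#' An inversion has flat-lined when its predicted response is (nearly)
#' constant while the data are not: the noise precision has absorbed all
#' the signal. Flagged when \code{var(predicted) < tol * var(observed)}
#' (strict inequality), variances pooled after per-region mean removal.
#'
#' @param predicted,observed [BOLDSeries-class] objects or matrices.
#' @param tol variance-ratio threshold, default \code{1e-3}.
#' @return logical flag.
#' @export
detectFlatline <- function(predicted, observed, tol = 1e-3) {
  yp <- if (is(predicted, "BOLDSeries")) boldMatrix(predicted) else as.matrix(predicted)
  yo <- if (is(observed, "BOLDSeries")) boldMatrix(observed) else as.matrix(observed)
  vp <- sum(scale(yp, scale = FALSE)^2)
  vo <- sum(scale(yo, scale = FALSE)^2)
  isTRUE(vp < tol * vo)
}

## ---------------------------------------------------------------------------
## Free energy
## ---------------------------------------------------------------------------

.klGaussian <- function(mu, Sigma, mu0, Sigma0) {
  p <- length(mu)
  if (p == 0L) return(0)
  ch0 <- chol(Sigma0)
  ch <- chol(Sigma)
  Sinv0 <- chol2inv(ch0)
  d <- mu - mu0
  0.5 * (sum(Sinv0 * Sigma) + drop(t(d) %*% Sinv0 %*% d) - p +
         2 * sum(log(diag(ch0))) - 2 * sum(log(diag(ch))))
}

#' Variational free energy from its components
#'
#' \eqn{F = } accuracy \eqn{-} complexity: the Gaussian log-likelihood of
#' the residuals under the (posterior mean) noise precision per region,
#' minus the KL divergences from posterior to prior for the parameters and
#' for the noise log-precisions. An optional \code{traceTerm} per region
#' adds the expected-sufficient-statistic correction
#' \eqn{tr(J \Sigma J^T)} that accounts for posterior parameter
#' uncertainty in the residual energy.
#'
#' @param residuals T-by-l matrix (observed minus predicted, per-region
#'   mean removed) or a vector for l = 1.
#' @param hMean per-region posterior mean noise log-precision.
#' @param postMean,postCov Gaussian posterior over the free parameters
#'   (omit both for a fixed-parameter evaluation; the parameter complexity
#'   is then zero).
#' @param priorMean,priorCov matching prior (diagonal covariance may be
#'   given as a vector of variances).
#' @param hVar,hPriorMean,hPriorVar posterior variance and prior over the
#'   noise log-precisions (omit \code{hVar} to treat the precision as
#'   fixed).
#' @param traceTerm per-region trace correction, default 0.
#' @return free energy in nats.
#' @export
freeEnergyVBL <- function(residuals, hMean, postMean = NULL, postCov = NULL,
                          priorMean = NULL, priorCov = NULL,
                          hVar = NULL, hPriorMean = NULL, hPriorVar = NULL,
                          traceTerm = 0) {
  r <- as.matrix(residuals)
  l <- ncol(r)
  N <- nrow(r)
  hMean <- rep_len(hMean, l)
  traceTerm <- rep_len(traceTerm, l)
  rss <- colSums(r^2)
  accuracy <- sum((N / 2) * (hMean - log(2 * pi)) -
                  (exp(hMean) / 2) * (rss + traceTerm))
  complexity <- 0
  if (!is.null(postMean) && !is.null(priorMean)) {
    if (is.vector(priorCov)) priorCov <- diag(priorCov, length(priorCov))
    if (is.vector(postCov)) postCov <- diag(postCov, length(postCov))
    complexity <- complexity + .klGaussian(postMean, postCov, priorMean, priorCov)
  }
  if (!is.null(hVar) && !is.null(hPriorMean)) {
    hVar <- rep_len(hVar, l)
    hPriorMean <- rep_len(hPriorMean, l)
    hPriorVar <- rep_len(hPriorVar, l)
    complexity <- complexity +
      sum(0.5 * ((hMean - hPriorMean)^2 / hPriorVar + hVar / hPriorVar - 1 +
                 log(hPriorVar / hVar)))
  }
  accuracy - complexity
}

## ---------------------------------------------------------------------------
## The VBL inversion
## ---------------------------------------------------------------------------

#' Fit a DCM by Variational Bayes under the Laplace assumption
#'
#' Iterated Gauss-Newton ascent on the free energy with
#' Levenberg-Marquardt damping. Sensitivities of the predicted BOLD
#' response to the free parameters are computed by forward finite
#' differences; an E-step (parameter update) alternates with an M-step
#' (per-region noise log-precision update by a 1-D Newton scheme).
#' A candidate step is accepted only if it increases F, so the recorded
#' F trajectory is non-decreasing; on rejection (including divergence of
#' the generative integration) the damping is doubled and the step
#' retried. Convergence is declared when the F improvement stays below
#' \code{tol} for 3 consecutive accepted iterations.
#'
#' Confound handling is per-region mean removal only: both data and
#' prediction are centred before the residual is formed.
#'
#' @param data observed [BOLDSeries-class].
#' @param inputs [InputTimeline-class], time-aligned with the data.
#' @param spec the [ModelSpec-class] to fit.
#' @param priors a [PriorSpec-class]; default [defaultPriors()].
#' @param hemo base hemodynamic constants (per-region kappa and tauH are
#'   scaled by the estimated log-scaling parameters).
#' @param opts list of options: \code{maxIter} (default 128), \code{tol}
#'   (F change, nats; default 1e-2), \code{damping0} (initial LM damping,
#'   default 1/8), \code{fdStep} (finite-difference step, default 1e-4),
#'   \code{maxReject} (default 8), \code{verbose}.
#' @return A [DCMPosterior-class].
#' @export
invertDCM <- function(data, inputs, spec, priors = defaultPriors(spec),
                      hemo = hemodynamicParams(), opts = list()) {
  o <- modifyList(list(maxIter = 128L, tol = 1e-2, damping0 = 1 / 8,
                       fdStep = 1e-4, maxReject = 8L, verbose = FALSE), opts)
  y <- boldMatrix(data)
  TR <- repetitionTime(data)
  l <- nRegions(spec)
  N <- nrow(y)
  yc <- scale(y, scale = FALSE)
  mu0 <- priors@mean
  v0 <- priors@variance
  nP <- length(mu0)
  h0 <- rep_len(priors@hMean, l)
  vh0 <- rep_len(priors@hVariance, l)
  duration <- N * TR

  ## pre-compile the integration grid and the theta unpacker
  lay <- .paramLayout(spec)
  stopifnot(identical(lay$name, names(mu0)))
  unpack <- .makeUnpacker(lay, spec, hemo)
  dtu <- inputs@dt
  stepsPerTR <- as.integer(round(TR / dtu))
  if (abs(TR / dtu - stepsPerTR) > 1e-8)
    stop("TR must be an integer multiple of the input microtime step")
  nSteps <- N * stepsPerTR
  tmicro <- (seq_len(nSteps) - 1L) * dtu
  U <- inputs@u[, pmin(floor(tmicro / dtu + 1e-9) + 1L, ncol(inputs@u)),
                drop = FALSE]
  sampleSteps <- as.integer(stepsPerTR * seq_len(N))

  predict <- function(theta) {
    nl <- unpack(theta)
    res <- .dcmIntegrateCpp(nl$neuro, nl$hemo, U, dtu, nSteps, sampleSteps,
                            FALSE)
    if (isTRUE(res$diverged)) NULL else res$y
  }

  theta <- mu0
  g0 <- predict(theta)
  if (is.null(g0))
    stop("inversion failure: generative model diverges at the prior mean")
  gc0 <- scale(g0, scale = FALSE)
  h <- h0
  Pi0 <- diag(1 / v0, nP)

  regionRows <- rep(seq_len(l), each = N)

  ## evaluate F for a candidate (theta-like quantities precomputed)
  evalF <- function(gc, Sigma, J, theta, h, hV) {
    r <- yc - gc
    tr <- vapply(seq_len(l), function(i) {
      Ji <- J[regionRows == i, , drop = FALSE]
      sum((Ji %*% Sigma) * Ji)
    }, 0)
    freeEnergyVBL(r, hMean = h, postMean = theta, postCov = Sigma,
                  priorMean = mu0, priorCov = diag(v0, nP),
                  hVar = hV, hPriorMean = h0, hPriorVar = vh0,
                  traceTerm = tr)
  }

  ## M-step: Newton update of per-region log-precision
  updateH <- function(h, rss, tr) {
    hV <- numeric(l)
    for (i in seq_len(l)) {
      hi <- h[i]
      for (it in 1:8) {
        e <- exp(hi) * (rss[i] + tr[i])
        g1 <- N / 2 - e / 2 - (hi - h0[i]) / vh0[i]
        g2 <- -e / 2 - 1 / vh0[i]
        step <- g1 / g2
        hi <- hi - step
        if (abs(step) < 1e-8) break
      }
      h[i] <- hi
      hV[i] <- 1 / (exp(hi) * (rss[i] + tr[i]) / 2 + 1 / vh0[i])
    }
    list(h = h, hVar = hV)
  }

  nu <- o$damping0
  Ftraj <- numeric(0)
  Fbest <- -Inf
  best <- NULL
  belowTol <- 0L
  converged <- FALSE
  iter <- 0L
  Fcur <- NA_real_

  while (iter < o$maxIter) {
    iter <- iter + 1L
    ## sensitivities at current theta
    J <- matrix(0, N * l, nP)
    for (k in seq_len(nP)) {
      th <- theta
      th[k] <- th[k] + o$fdStep
      gk <- predict(th)
      if (!is.null(gk))
        J[, k] <- (c(scale(gk, scale = FALSE)) - c(gc0)) / o$fdStep
    }
    lam <- exp(h)
    JtLJ <- matrix(0, nP, nP)
    JtLr <- numeric(nP)
    rcur <- yc - gc0
    for (i in seq_len(l)) {
      Ji <- J[regionRows == i, , drop = FALSE]
      JtLJ <- JtLJ + lam[i] * crossprod(Ji)
      JtLr <- JtLr + lam[i] * drop(crossprod(Ji, rcur[, i]))
    }
    Hbase <- JtLJ + Pi0
    grad <- JtLr - drop(Pi0 %*% (theta - mu0))

    ## current-F reference for the acceptance rule on the first iteration
    if (iter == 1L) {
      Sig0 <- tryCatch(chol2inv(chol(Hbase)), error = function(e) NULL)
      if (is.null(Sig0)) stop("numerical-conditioning error: singular curvature")
      rss <- colSums(rcur^2)
      tr0 <- vapply(seq_len(l), function(i) {
        Ji <- J[regionRows == i, , drop = FALSE]
        sum((Ji %*% Sig0) * Ji)
      }, 0)
      hu <- updateH(h, rss, tr0)
      h <- hu$h
      Fcur <- evalF(gc0, Sig0, J, theta, h, hu$hVar)
      Fbest <- Fcur
      best <- list(theta = theta, Sigma = Sig0, h = h, hVar = hu$hVar, g = g0)
      Ftraj <- Fcur
    }

    accepted <- FALSE
    for (try in seq_len(o$maxReject)) {
      Hd <- Hbase + nu * diag(diag(Hbase), nP)
      step <- tryCatch(solve(Hd, grad), error = function(e) NULL)
      if (is.null(step)) { nu <- nu * 2; next }
      thNew <- theta + step
      gNew <- predict(thNew)
      if (is.null(gNew)) { nu <- nu * 2; next }
      gcNew <- scale(gNew, scale = FALSE)
      SigNew <- tryCatch(chol2inv(chol(Hbase)), error = function(e) NULL)
      if (is.null(SigNew)) { nu <- nu * 2; next }
      rNew <- yc - gcNew
      rss <- colSums(rNew^2)
      trN <- vapply(seq_len(l), function(i) {
        Ji <- J[regionRows == i, , drop = FALSE]
        sum((Ji %*% SigNew) * Ji)
      }, 0)
      hu <- updateH(h, rss, trN)
      FNew <- evalF(gcNew, SigNew, J, thNew, hu$h, hu$hVar)
      if (is.finite(FNew) && FNew > Fcur) {
        dF <- FNew - Fcur
        theta <- thNew; g0 <- gNew; gc0 <- gcNew
        h <- hu$h
        Fcur <- FNew
        nu <- max(nu / 2, 1e-8)
        Ftraj <- c(Ftraj, FNew)
        if (FNew > Fbest) {
          Fbest <- FNew
          best <- list(theta = theta, Sigma = SigNew, h = h,
                       hVar = hu$hVar, g = g0)
        }
        belowTol <- if (dF < o$tol) belowTol + 1L else 0L
        accepted <- TRUE
        if (o$verbose)
          message(sprintf("iter %d: F = %.3f (dF = %.4f, nu = %.3g)",
                          iter, FNew, dF, nu))
        break
      }
      nu <- nu * 2
    }
    if (!accepted) { converged <- TRUE; break }
    if (belowTol >= 3L) { converged <- TRUE; break }
  }

  predBold <- boldSeries(best$g, TR = TR, regionNames = regionNames(data))
  ev <- explainedVariance(data, predBold)
  fl <- detectFlatline(predBold, data)
  Sigma <- (best$Sigma + t(best$Sigma)) / 2
  dimnames(Sigma) <- list(names(mu0), names(mu0))
  new("DCMPosterior",
      mean = setNames(best$theta, names(mu0)), cov = Sigma,
      hMean = best$h, hVar = best$hVar,
      freeEnergy = Fbest, Ftrajectory = Ftraj,
      predicted = predBold, explainedVariance = ev,
      nIterations = iter, converged = converged, flatline = fl,
      spec = spec)
}

## ---------------------------------------------------------------------------
## Posterior summaries
## ---------------------------------------------------------------------------

#' Posterior probability that each parameter is nonzero
#'
#' Under the Gaussian posterior marginal of each free parameter, returns
#' \code{max(Pr(theta > 0), Pr(theta < 0))} — the posterior confidence in
#' the parameter's sign, used as the connection presence score downstream.
#'
#' @param posterior a [DCMPosterior-class].
#' @param pattern optional regular expression to select parameters by name.
#' @return named numeric vector of probabilities.
#' @export
signProbabilities <- function(posterior, pattern = NULL) {
  mu <- posterior@mean
  sdv <- sqrt(pmax(diag(posterior@cov), 0))
  p <- ifelse(sdv > 0,
              pmax(pnorm(mu / pmax(sdv, 1e-300)),
                   pnorm(-mu / pmax(sdv, 1e-300))),
              as.numeric(mu != 0))
  if (!is.null(pattern)) p <- p[grepl(pattern, names(p))]
  p
}

#' Presence scores for inter-regional connections
#'
#' Extracts the posterior sign probability of every off-diagonal coupling
#' parameter (\code{A[i,j]} for single-state models, \code{logwEE[i,j]} on
#' the log scale for two-state models), named \code{"i<-j"}.
#'
#' @param posterior a [DCMPosterior-class].
#' @return named numeric vector over candidate directed edges.
#' @export
connectionScores <- function(posterior) {
  lay <- .paramLayout(posterior@spec)
  grp <- if (posterior@spec@states == "one") "A" else "logwEE"
  sel <- lay$group == grp & lay$i != lay$j
  p <- signProbabilities(posterior)[lay$name[sel]]
  names(p) <- sprintf("%d<-%d", lay$i[sel], lay$j[sel])
  p
}
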
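## Forward model: neuronal + hemodynamic cascade integrated with fixed-step
## RK4 on a microtime grid, BOLD sampled at the repetition time; plus the
## three-region ground-truth network and the seeded synthetic-data generator.

.applyMasks <- function(spec, p) {
  l <- nRegions(spec)
  if (spec@states == "one") {
    stopifnot(is(p, "NeuronalParams"))
    A <- p@A * spec@Amask
    B <- lapply(seq_len(spec@nInputs),
                function(j) p@B[[j]] * spec@Bmasks[[j]])
    C <- p@Cin * spec@Cmask
    new("NeuronalParams", A = A, B = B, Cin = C,
        alpha = rep_len(p@alpha, l))
  } else {
    stopifnot(is(p, "TwoStateParams"))
    off <- spec@Amask & !diag(l)
    wEE <- p@wEE * off
    bEE <- lapply(seq_len(spec@nInputs),
                  function(j) p@bEE[[j]] * (spec@Bmasks[[j]] & off))
    bIE <- lapply(seq_len(spec@nInputs),
                  function(j) p@bIE[[j]] * diag(spec@Bmasks[[j]]))
    C <- p@Cin * spec@Cmask
    new("TwoStateParams", wEE = wEE, bEE = bEE, wSE = p@wSE, wSI = p@wSI,
        wIE = p@wIE, wEI = p@wEI, bIE = bIE, Cin = C,
        alphaE = p@alphaE, alphaI = p@alphaI)
  }
}

.neuroList <- function(spec, p) {
  l <- nRegions(spec)
  if (spec@states == "one")
    list(variant = if (spec@variant == "bilinear") 0L else 1L, states = 1L,
         l = l, m = spec@nInputs, A = p@A, B = p@B, C = p@Cin,
         alpha = rep_len(p@alpha, l))
  else
    list(variant = if (spec@variant == "bilinear") 0L else 1L, states = 2L,
         l = l, m = spec@nInputs, wEE = p@wEE, bEE = p@bEE,
         wSE = p@wSE, wSI = p@wSI, wIE = p@wIE, wEI = p@wEI, bIE = p@bIE,
         C = p@Cin, alphaE = p@alphaE, alphaI = p@alphaI)
}

.hemoList <- function(hp, l) {
  list(kappa = rep_len(hp@kappa, l), gamma = rep_len(hp@gamma, l),
       tauH = rep_len(hp@tauH, l), alphaG = hp@alphaG, rho = hp@rho,
       V0 = hp@V0, k1 = hp@k1, k2 = hp@k2, k3 = hp@k3)
}

#' Integrate a DCM forward in time
#'
#' Runs the full neuronal + balloon/windkessel cascade from the resting
#' fixed point (all neuronal states zero; s = 0, f = v = q = 1) with
#' fixed-step RK4 on the microtime grid, and samples the BOLD observation
#' at repetition-time instants \code{TR, 2 TR, ...}. Inputs are
#' zero-order-held: the input grid is resampled deterministically onto the
#' integration grid, so the result is unchanged when \code{dt} divides the
#' input step. Deterministic given inputs.
#'
#' @param spec a [ModelSpec-class] selecting the neuronal equation.
#' @param neuronal [NeuronalParams-class] or [TwoStateParams-class]
#'   (matching \code{spec}'s \code{states}); entries outside the structural
#'   masks are zeroed before integration.
#' @param hemo a [HemodynamicParams-class].
#' @param inputs an [InputTimeline-class].
#' @param TR repetition time in seconds.
#' @param duration total simulated time (s); default: the input timeline's
#'   extent.
#' @param dt integration step (s); default: the input timeline's microtime
#'   step. \code{TR} must be an integer multiple of \code{dt}.
#' @param keepLatent if \code{TRUE}, also return the neuronal states at the
#'   sample instants.
#' @return list with \code{bold} (a [BOLDSeries-class]) and \code{latent}
#'   (a samples-by-states matrix, or \code{NULL}).
#' @section Divergence: linear (bilinear) dynamics with unstable coupling
#'   can blow up; a non-finite or huge state aborts integration with a
#'   condition of class \code{"dcmDivergenceError"} carrying the first bad
#'   microtime step in \code{$step}. Wilson-Cowan dynamics are globally
#'   bounded and do not trigger this under bounded inputs.
#' @export
integrateDCM <- function(spec, neuronal, hemo = hemodynamicParams(),
                         inputs, TR, duration = NULL, dt = NULL,
                         keepLatent = FALSE) {
  stopifnot(is(spec, "ModelSpec"), is(inputs, "InputTimeline"))
  if (spec@nInputs != nrow(inputs@u))
    stop("shape error: timeline has ", nrow(inputs@u),
         " input(s) but spec declares ", spec@nInputs)
  p <- .applyMasks(spec, neuronal)
  dtu <- inputs@dt
  if (is.null(dt)) dt <- dtu
  if (is.null(duration)) duration <- ncol(inputs@u) * dtu
  stepsPerTR <- TR / dt
  if (abs(stepsPerTR - round(stepsPerTR)) > 1e-8)
    stop("TR must be an integer multiple of dt")
  stepsPerTR <- as.integer(round(stepsPerTR))
  nSamp <- as.integer(floor(duration / TR + 1e-9))
  nSteps <- nSamp * stepsPerTR
  ## resample inputs onto the integration grid (zero-order hold)
  tmicro <- (seq_len(nSteps) - 1L) * dt
  cols <- pmin(floor(tmicro / dtu + 1e-9) + 1L, ncol(inputs@u))
  U <- inputs@u[, cols, drop = FALSE]
  res <- .dcmIntegrateCpp(.neuroList(spec, p), .hemoList(hemo, nRegions(spec)),
                          U, dt, nSteps,
                          as.integer(stepsPerTR * seq_len(nSamp)), keepLatent)
  if (isTRUE(res$diverged))
    stop(errorCondition(
      sprintf("divergence error: non-finite state at microtime step %d (t = %.3f s)",
              res$badStep, res$badStep * dt),
      step = res$badStep, class = c("dcmDivergenceError", "error")))
  bold <- boldSeries(res$y, TR = TR, regionNames = regionNames(spec))
  list(bold = bold,
       latent = if (keepLatent) res$latent else NULL)
}

#' The three-region ground-truth benchmark network
#'
#' The synthetic benchmark used throughout the evaluation harness: three
#' regions with one driving input into region 1, feedforward connections
#' 1 -> 2 and 1 -> 3, a forward connection 3 -> 2, and a contextual
#' (modulatory) input acting on 1 -> 3 and 3 -> 2. Input 1 is the driving
#' input, input 2 the contextual one.
#'
#' Default numeric values (all overridable): self-connections
#' \code{-0.5} Hz, forward edges \code{0.4} Hz, modulations \code{0.2} Hz,
#' driving input \code{0.5} Hz, sigmoid slope 4.
#'
#' @param variant neuronal equation of the generating model.
#' @param selfStrength,forward,modulation,driving,alpha numeric values for
#'   the parameter groups described above.
#' @return list with \code{spec} ([ModelSpec-class], single-state) and
#'   \code{neuronal} ([NeuronalParams-class]).
#' @examples
#' gt <- groundTruthNetwork()
#' which(connectionMask(gt$spec) & !diag(3))  # the three directed edges
#' @export
groundTruthNetwork <- function(variant = c("bilinear", "wilson_cowan"),
                               selfStrength = -0.5, forward = 0.4,
                               modulation = 0.2, driving = 0.5, alpha = 4) {
  variant <- match.arg(variant)
  l <- 3L
  Amask <- diag(l) == 1
  Amask[2, 1] <- Amask[3, 1] <- Amask[2, 3] <- TRUE
  B2 <- matrix(FALSE, l, l)
  B2[3, 1] <- B2[2, 3] <- TRUE
  Cmask <- matrix(FALSE, l, 2)
  Cmask[1, 1] <- TRUE
  spec <- modelSpec(c("R1", "R2", "R3"), Amask,
                    Bmasks = list(matrix(FALSE, l, l), B2), Cmask,
                    variant = variant, states = "one")
  A <- diag(rep(selfStrength, l))
  A[2, 1] <- A[3, 1] <- A[2, 3] <- forward
  Bmod <- matrix(0, l, l)
  Bmod[3, 1] <- Bmod[2, 3] <- modulation
  C <- matrix(0, l, 2)
  C[1, 1] <- driving
  list(spec = spec,
       neuronal = neuronalParams(A, B = list(matrix(0, l, l), Bmod), C,
                                 alpha = alpha))
}

#' Standard benchmark input timelines
#'
#' The fixture design used for synthetic runs: a driving boxcar alternating
#' 20 s off / 20 s on, and a slow contextual boxcar with a 60 s period
#' (30 s off / 30 s on), both 0/1 valued on the microtime grid.
#'
#' @param duration run length in seconds (default 360, a 6-minute run).
#' @param dt microtime step in seconds (default \code{2/16}, i.e. TR/16 at
#'   TR = 2 s).
#' @return An [InputTimeline-class] with inputs \code{driving} and
#'   \code{context}.
#' @export
standardInputs <- function(duration = 360, dt = 2 / 16) {
  t <- seq(0, duration - dt, by = dt)
  driving <- as.numeric((t %% 40) >= 20)
  context <- as.numeric((t %% 60) >= 30)
  inputTimeline(rbind(driving, context), dt = dt,
                inputNames = c("driving", "context"))
}

#' Generate a seeded synthetic dataset at a fixed SNR
#'
#' Integrates the model once to obtain the noise-free BOLD series, then
#' adds \code{nReal} independent realizations of white Gaussian noise. SNR
#' is defined per region as sd(signal)/sd(noise), so the noise standard
#' deviation in region i is \code{sd(clean[, i]) / snr}; \code{snr = Inf}
#' returns the clean series unchanged. Fully reproducible from \code{seed}.
#'
#' @param spec,neuronal,hemo,inputs the generating model, as in
#'   [integrateDCM()].
#' @param snr positive signal-to-noise ratio, or \code{Inf}.
#' @param nReal number of noisy realizations (>= 1).
#' @param seed integer seed.
#' @param TR repetition time (s).
#' @param duration run length (s); default from the input timeline.
#' @return A [SyntheticDataset-class].
#' @export
simulateDataset <- function(spec, neuronal, hemo = hemodynamicParams(),
                            inputs, snr, nReal = 10L, seed = 1L,
                            TR = 2, duration = NULL) {
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop("invalid parameter: snr must be positive (or Inf)")
  if (nReal < 1L) stop("invalid parameter: nReal must be >= 1")
  clean <- integrateDCM(spec, neuronal, hemo, inputs, TR = TR,
                        duration = duration)$bold
  y <- boldMatrix(clean)
  noisy <- if (is.infinite(snr)) {
    replicate(nReal, clean, simplify = FALSE)
  } else {
    sds <- apply(y, 2, sd) / snr
    set.seed(as.integer(seed))
    lapply(seq_len(nReal), function(r) {
      noise <- sweep(matrix(rnorm(length(y)), nrow(y), ncol(y)), 2, sds, `*`)
      boldSeries(y + noise, TR = repetitionTime(clean),
                 regionNames = regionNames(clean))
    })
  }
  new("SyntheticDataset", spec = spec, neuronal = neuronal, hemo = hemo,
      inputs = inputs, clean = clean, noisy = noisy, snr = snr,
      seed = as.integer(seed))
}
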
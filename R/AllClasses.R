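#' @import methods
#' @importFrom stats var sd rnorm pnorm qnorm dnorm cor quantile setNames
#' @importFrom utils head tail read.table write.table
NULL

## ---------------------------------------------------------------------------
## ModelSpec: the structural definition of one DCM
## ---------------------------------------------------------------------------

#' Structural specification of a dynamic causal model
#'
#' A \code{ModelSpec} fixes the structure of one DCM: which directed
#' connections between regions exist (\code{Amask}), which of them each
#' modulatory input may change (\code{Bmasks}), which regions receive a
#' driving input (\code{Cmask}), and which neuronal state equation is used
#' (\code{variant}: classical bilinear or Wilson-Cowan sigmoid;
#' \code{states}: a single neuronal state per region or separate
#' excitatory/inhibitory sub-populations).
#'
#' Orientation convention: \code{Amask[i, j]} (and \code{A[i, j]} in
#' [neuronalParams()]) is the connection \emph{from region j to region i}
#' (rows index the target). Self-connections are always present and never
#' modulated; modulation is only allowed on existing connections.
#'
#' @slot regionNames character vector of region labels (length \code{l}).
#' @slot nInputs number of experimental inputs \code{m}.
#' @slot Amask l-by-l logical; \code{TRUE} where a connection exists.
#' @slot Bmasks list of \code{m} l-by-l logicals; \code{TRUE} where the
#'   corresponding input modulates a connection.
#' @slot Cmask l-by-m logical; \code{TRUE} where an input drives a region.
#' @slot variant \code{"bilinear"} or \code{"wilson_cowan"}.
#' @slot states \code{"one"} or \code{"two"}.
#' @seealso [modelSpec()], [groundTruthNetwork()], [enumerateFull()]
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(
    regionNames = "character",
    nInputs     = "integer",
    Amask       = "matrix",
    Bmasks      = "list",
    Cmask       = "matrix",
    variant     = "character",
    states      = "character"
  )
)

setValidity("ModelSpec", function(object) {
  l <- length(object@regionNames)
  m <- object@nInputs
  msg <- character()
  if (l < 1L) msg <- c(msg, "at least one region is required")
  if (m < 1L) msg <- c(msg, "at least one input is required")
  if (!identical(dim(object@Amask), c(l, l)))
    msg <- c(msg, "Amask must be l x l")
  if (!is.logical(object@Amask)) msg <- c(msg, "Amask must be logical")
  if (!identical(dim(object@Cmask), c(l, m)))
    msg <- c(msg, "Cmask must be l x m")
  if (length(object@Bmasks) != m)
    msg <- c(msg, "need one Bmask per input")
  if (!length(msg) && !all(diag(object@Amask)))
    msg <- c(msg, "self-connections (Amask diagonal) must all be present")
  for (Bm in object@Bmasks) {
    if (!identical(dim(Bm), c(l, l))) { msg <- c(msg, "Bmask must be l x l"); break }
    if (any(Bm & !object@Amask)) {
      msg <- c(msg, "modulation allowed only on existing connections (Bmask implies Amask)")
      break
    }
  }
  if (!object@variant %in% c("bilinear", "wilson_cowan"))
    msg <- c(msg, "variant must be 'bilinear' or 'wilson_cowan'")
  if (!object@states %in% c("one", "two"))
    msg <- c(msg, "states must be 'one' or 'two'")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelSpec
#'
#' @param regionNames character vector of region labels.
#' @param Amask l-by-l logical connection mask (diagonal forced \code{TRUE}).
#' @param Bmasks a single l-by-l logical or a list of one per input.
#' @param Cmask l-by-m logical driving-input mask.
#' @param variant neuronal equation: \code{"bilinear"} or \code{"wilson_cowan"}.
#' @param states \code{"one"} (single neuronal state per region) or
#'   \code{"two"} (excitatory/inhibitory sub-populations).
#' @return A validated [ModelSpec-class] object.
#' @examples
#' sp <- modelSpec(c("R1", "R2"),
#'                 Amask = matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2),
#'                 Bmasks = matrix(FALSE, 2, 2),
#'                 Cmask = matrix(c(TRUE, FALSE), 2, 1))
#' nRegions(sp)
#' @export
modelSpec <- function(regionNames, Amask, Bmasks, Cmask,
                      variant = c("wilson_cowan", "bilinear"),
                      states = c("one", "two")) {
  variant <- match.arg(variant)
  states <- match.arg(states)
  l <- length(regionNames)
  Amask <- matrix(as.logical(Amask), l, l)
  diag(Amask) <- TRUE
  if (is.matrix(Bmasks)) Bmasks <- list(Bmasks)
  Bmasks <- lapply(Bmasks, function(b) matrix(as.logical(b), l, l))
  Cmask <- as.matrix(Cmask)
  storage.mode(Cmask) <- "logical"
  new("ModelSpec", regionNames = as.character(regionNames),
      nInputs = ncol(Cmask), Amask = Amask, Bmasks = Bmasks,
      Cmask = Cmask, variant = variant, states = states)
}

## ---------------------------------------------------------------------------
## Parameters
## ---------------------------------------------------------------------------

#' Neuronal parameters of a single-state DCM
#'
#' Holds the coupling matrices of the single-state neuronal equation:
#' \code{A} (fixed connectivity, Hz), \code{B} (per-input modulation, Hz),
#' \code{C} (driving inputs, Hz) and, for the Wilson-Cowan variant, the
#' per-region sigmoid slope \code{alpha} (dimensionless, strictly positive).
#' Entries are zero wherever the corresponding [ModelSpec-class] mask is
#' \code{FALSE}.
#'
#' @slot A l-by-l numeric coupling matrix (Hz).
#' @slot B list of l-by-l numeric modulation matrices, one per input (Hz).
#' @slot Cin l-by-m numeric driving-input matrix (Hz).
#' @slot alpha numeric vector of sigmoid slopes, length l (or length 1,
#'   shared across regions).
#' @exportClass NeuronalParams
setClass("NeuronalParams",
  representation(A = "matrix", B = "list", Cin = "matrix", alpha = "numeric"))

setValidity("NeuronalParams", function(object) {
  l <- nrow(object@A)
  if (ncol(object@A) != l) return("A must be square")
  for (Bj in object@B)
    if (!identical(dim(Bj), dim(object@A))) return("each B must match A")
  if (nrow(object@Cin) != l) return("C must have one row per region")
  if (any(object@alpha <= 0)) return("alpha must be strictly positive")
  if (!length(object@alpha) %in% c(1L, l))
    return("alpha must have length 1 or one entry per region")
  if (!all(is.finite(object@A)) || !all(is.finite(object@Cin)))
    return("parameters must be finite")
  TRUE
})

#' Construct single-state neuronal parameters
#'
#' @param A l-by-l coupling matrix (Hz); \code{A[i, j]} couples region j to i.
#' @param B modulation matrix or list of matrices, one per input (Hz).
#' @param C l-by-m driving-input matrix (Hz).
#' @param alpha sigmoid slope(s), strictly positive; used by the
#'   Wilson-Cowan variant only. Length 1 (shared) or one per region.
#' @return A [NeuronalParams-class] object.
#' @export
neuronalParams <- function(A, B = NULL, C, alpha = 4) {
  A <- as.matrix(A)
  l <- nrow(A)
  C <- as.matrix(C)
  if (is.null(B)) B <- replicate(ncol(C), matrix(0, l, l), simplify = FALSE)
  if (is.matrix(B)) B <- list(B)
  new("NeuronalParams", A = A, B = lapply(B, as.matrix), Cin = C,
      alpha = as.numeric(alpha))
}

#' Neuronal parameters of a two-state (E/I) DCM
#'
#' Per-region excitatory and inhibitory sub-populations. Inter-regional
#' coupling is carried exclusively by the excitatory populations through
#' \code{wEE} (one weight per directed edge); \code{wSE}, \code{wSI},
#' \code{wIE}, \code{wEI} are intrinsic per-region weights. All weights are
#' positive; the sign structure (inhibition enters E negatively, E drives I
#' positively) is written into the state equation itself. Modulatory inputs
#' act as multiplicative factors \code{exp(b * u)} on \code{wEE} (edge-wise,
#' off-diagonal modulation masks) and on \code{wIE} (region-wise, diagonal
#' modulation masks).
#'
#' @slot wEE l-by-l non-negative matrix; off-diagonal inter-regional E-to-E
#'   weights (Hz). The diagonal is ignored (self-excitation is \code{wSE}).
#' @slot bEE list (one per input) of l-by-l modulation exponents on wEE.
#' @slot wSE,wSI,wIE,wEI per-region positive intrinsic weights (Hz).
#' @slot bIE list (one per input) of per-region modulation exponents on wIE.
#' @slot Cin l-by-m driving-input matrix (Hz), entering the excitatory state.
#' @slot alphaE,alphaI sigmoid slopes for the E and I populations
#'   (Wilson-Cowan variant only), strictly positive.
#' @exportClass TwoStateParams
setClass("TwoStateParams",
  representation(wEE = "matrix", bEE = "list",
                 wSE = "numeric", wSI = "numeric",
                 wIE = "numeric", wEI = "numeric", bIE = "list",
                 Cin = "matrix", alphaE = "numeric", alphaI = "numeric"))

setValidity("TwoStateParams", function(object) {
  l <- nrow(object@wEE)
  if (ncol(object@wEE) != l) return("wEE must be square")
  for (nm in c("wSE", "wSI", "wIE", "wEI"))
    if (length(slot(object, nm)) != l)
      return(sprintf("%s must have one entry per region", nm))
  if (any(object@wSE < 0) || any(object@wSI < 0) ||
      any(object@wIE < 0) || any(object@wEI < 0) ||
      any(object@wEE[row(object@wEE) != col(object@wEE)] < 0))
    return("two-state weights must be non-negative")
  if (any(object@alphaE <= 0) || any(object@alphaI <= 0))
    return("alphaE and alphaI must be strictly positive")
  if (nrow(object@Cin) != l) return("C must have one row per region")
  TRUE
})

#' Construct two-state neuronal parameters
#'
#' @param wEE l-by-l inter-regional excitatory coupling (Hz); diagonal unused.
#' @param wSE,wSI,wIE,wEI per-region intrinsic weights (Hz), recycled to
#'   length l.
#' @param C l-by-m driving-input matrix (Hz).
#' @param bEE,bIE modulation exponents (lists, one element per input):
#'   l-by-l matrices for \code{bEE}, length-l vectors for \code{bIE}.
#'   Default: no modulation.
#' @param alphaE,alphaI sigmoid slopes (Wilson-Cowan variant), recycled to
#'   length l.
#' @return A [TwoStateParams-class] object.
#' @export
twoStateParams <- function(wEE, wSE = 0.5, wSI = 0.5, wIE = 0.5, wEI = 0.5,
                           C, bEE = NULL, bIE = NULL,
                           alphaE = 4, alphaI = 4) {
  wEE <- as.matrix(wEE)
  l <- nrow(wEE)
  C <- as.matrix(C)
  m <- ncol(C)
  if (is.null(bEE)) bEE <- replicate(m, matrix(0, l, l), simplify = FALSE)
  if (is.matrix(bEE)) bEE <- list(bEE)
  if (is.null(bIE)) bIE <- replicate(m, numeric(l), simplify = FALSE)
  if (is.numeric(bIE) && !is.list(bIE)) bIE <- list(bIE)
  new("TwoStateParams", wEE = wEE, bEE = bEE,
      wSE = rep_len(wSE, l), wSI = rep_len(wSI, l),
      wIE = rep_len(wIE, l), wEI = rep_len(wEI, l),
      bIE = lapply(bIE, function(b) rep_len(b, l)),
      Cin = C, alphaE = rep_len(alphaE, l), alphaI = rep_len(alphaI, l))
}

#' Balloon/windkessel hemodynamic constants
#'
#' Per-region constants of the hemodynamic cascade converting neuronal
#' activity into the BOLD signal: vasodilatory signal decay \code{kappa}
#' (1/s), flow autoregulation \code{gamma} (1/s), mean venous transit time
#' \code{tauH} (s), Grubb's vessel stiffness exponent \code{alphaG},
#' resting oxygen extraction fraction \code{rho}, resting venous volume
#' fraction \code{V0}, and the observation coefficients \code{k1, k2, k3}.
#'
#' @slot kappa,gamma,tauH per-region rates/times (recycled as needed).
#' @slot alphaG,rho,V0,k1,k2,k3 scalars.
#' @exportClass HemodynamicParams
setClass("HemodynamicParams",
  representation(kappa = "numeric", gamma = "numeric", tauH = "numeric",
                 alphaG = "numeric", rho = "numeric", V0 = "numeric",
                 k1 = "numeric", k2 = "numeric", k3 = "numeric"))

setValidity("HemodynamicParams", function(object) {
  pos <- c(object@kappa, object@gamma, object@tauH, object@V0)
  if (any(pos <= 0)) return("kappa, gamma, tauH, V0 must be positive")
  if (object@alphaG <= 0 || object@alphaG >= 1)
    return("alphaG must lie in (0, 1)")
  if (object@rho <= 0 || object@rho >= 1) return("rho must lie in (0, 1)")
  TRUE
})

#' Default hemodynamic constants
#'
#' Classical balloon/windkessel constants at 1.5 T: \code{kappa = 0.64} 1/s,
#' \code{gamma = 0.32} 1/s, \code{tauH = 2} s, \code{alphaG = 0.32},
#' \code{rho = 0.32}, \code{V0 = 0.04}, with observation coefficients
#' \code{k1 = 7 rho}, \code{k2 = 2}, \code{k3 = 2 rho - 0.2}. All
#' overridable.
#'
#' @param kappa,gamma,tauH,alphaG,rho,V0,k1,k2,k3 see
#'   [HemodynamicParams-class].
#' @return A [HemodynamicParams-class] object.
#' @export
hemodynamicParams <- function(kappa = 0.64, gamma = 0.32, tauH = 2.0,
                              alphaG = 0.32, rho = 0.32, V0 = 0.04,
                              k1 = 7 * rho, k2 = 2, k3 = 2 * rho - 0.2) {
  new("HemodynamicParams", kappa = kappa, gamma = gamma, tauH = tauH,
      alphaG = alphaG, rho = rho, V0 = V0, k1 = k1, k2 = k2, k3 = k3)
}

## ---------------------------------------------------------------------------
## Timelines and series
## ---------------------------------------------------------------------------

#' Experimental input timeline on the microtime grid
#'
#' Inputs (typically 0/1 boxcars) sampled on a grid finer than the scan
#' repetition time. \code{u} has one row per input and one column per
#' microtime step; the value in column k applies on the interval
#' \code{[(k-1) dt, k dt)}.
#'
#' @slot dt microtime step in seconds.
#' @slot u m-by-T numeric matrix of input values.
#' @slot inputNames character labels, length m.
#' @seealso [inputTimeline()], [eventsToTimeline()]
#' @exportClass InputTimeline
setClass("InputTimeline",
  representation(dt = "numeric", u = "matrix", inputNames = "character"))

setValidity("InputTimeline", function(object) {
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    return("dt must be a single positive number")
  if (!all(is.finite(object@u))) return("input values must be finite")
  if (length(object@inputNames) != nrow(object@u))
    return("need one name per input row")
  TRUE
})

#' Construct an input timeline from sampled values
#'
#' @param u m-by-T matrix (or a vector, taken as one input) of input values.
#' @param dt microtime step (s).
#' @param inputNames optional labels.
#' @return An [InputTimeline-class].
#' @export
inputTimeline <- function(u, dt, inputNames = NULL) {
  if (is.vector(u)) u <- matrix(u, nrow = 1)
  if (is.null(inputNames))
    inputNames <- rownames(u) %||% paste0("u", seq_len(nrow(u)))
  new("InputTimeline", dt = dt, u = u, inputNames = as.character(inputNames))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Region-averaged BOLD time series
#'
#' Observed or simulated BOLD signal in percent signal change, sampled at a
#' fixed repetition time. Stored as a samples-by-regions matrix (column
#' order is region order everywhere in the package).
#'
#' @slot TR repetition time in seconds.
#' @slot y T-by-l numeric matrix (% signal change).
#' @slot regionNames character labels, length l.
#' @seealso [boldSeries()], [readBoldTsv()], [writeBoldTsv()]
#' @exportClass BOLDSeries
setClass("BOLDSeries",
  representation(TR = "numeric", y = "matrix", regionNames = "character"))

setValidity("BOLDSeries", function(object) {
  if (length(object@TR) != 1L || object@TR <= 0)
    return("TR must be a single positive number")
  if (anyNA(object@y)) return("BOLD series must not contain missing values")
  if (length(object@regionNames) != ncol(object@y))
    return("need one region name per column")
  TRUE
})

#' Construct a BOLD series
#'
#' @param y T-by-l matrix of samples (rows) by regions (columns).
#' @param TR repetition time (s).
#' @param regionNames optional labels (default: column names or R1, R2, ...).
#' @return A [BOLDSeries-class].
#' @export
boldSeries <- function(y, TR, regionNames = NULL) {
  y <- as.matrix(y)
  if (is.null(regionNames))
    regionNames <- colnames(y) %||% paste0("R", seq_len(ncol(y)))
  colnames(y) <- regionNames
  new("BOLDSeries", TR = TR, y = y, regionNames = as.character(regionNames))
}

#' A seeded synthetic dataset at one SNR
#'
#' Bundles the generating model, its parameters, the noise-free BOLD series
#' and a list of noisy realizations sharing that clean series. SNR is
#' defined per region as sd(signal)/sd(noise); \code{snr = Inf} means no
#' noise is added.
#'
#' @slot spec the generating [ModelSpec-class].
#' @slot neuronal generating neuronal parameters.
#' @slot hemo generating [HemodynamicParams-class].
#' @slot inputs the [InputTimeline-class] used.
#' @slot clean noise-free [BOLDSeries-class].
#' @slot noisy list of noisy [BOLDSeries-class] realizations.
#' @slot snr positive real or \code{Inf}.
#' @slot seed integer seed the realizations were drawn from.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(spec = "ModelSpec", neuronal = "ANY",
                 hemo = "HemodynamicParams", inputs = "InputTimeline",
                 clean = "BOLDSeries", noisy = "list",
                 snr = "numeric", seed = "integer"))

## ---------------------------------------------------------------------------
## Inversion containers
## ---------------------------------------------------------------------------

#' Prior specification over the free parameters of one DCM
#'
#' Shrinkage priors on the unconstrained parameter scale. Parameters whose
#' structural mask is \code{FALSE} are pinned: they carry prior variance 0
#' and are excluded from the free-parameter vector.
#'
#' @slot mean named numeric vector of prior means (free parameters only).
#' @slot variance named numeric vector of prior variances (diagonal prior).
#' @slot hMean,hVariance prior mean and variance of the per-region noise
#'   log-precision.
#' @slot spec the [ModelSpec-class] the priors are laid out for.
#' @seealso [defaultPriors()]
#' @exportClass PriorSpec
setClass("PriorSpec",
  representation(mean = "numeric", variance = "numeric",
                 hMean = "numeric", hVariance = "numeric",
                 spec = "ModelSpec"))

setValidity("PriorSpec", function(object) {
  if (length(object@mean) != length(object@variance))
    return("mean and variance must align")
  if (any(object@variance < 0)) return("variances must be non-negative")
  if (any(object@hVariance <= 0)) return("hyperprior variance must be positive")
  TRUE
})

#' Variational-Laplace posterior over one DCM
#'
#' Output of [invertDCM()]: a Gaussian (Laplace) posterior over the free
#' parameters, per-region noise log-precision posteriors, the free energy F
#' (nats; variational lower bound on log model evidence), the predicted
#' response, explained variance, and convergence/flat-line diagnostics.
#'
#' @slot mean,cov posterior mean (named) and covariance over free parameters.
#' @slot hMean,hVar per-region posterior mean/variance of noise log-precision.
#' @slot freeEnergy free energy F in nats.
#' @slot Ftrajectory F after each accepted iteration.
#' @slot predicted predicted [BOLDSeries-class].
#' @slot explainedVariance percent of observed variance explained.
#' @slot nIterations,converged,flatline diagnostics.
#' @slot spec the fitted [ModelSpec-class].
#' @exportClass DCMPosterior
setClass("DCMPosterior",
  representation(mean = "numeric", cov = "matrix",
                 hMean = "numeric", hVar = "numeric",
                 freeEnergy = "numeric", Ftrajectory = "numeric",
                 predicted = "BOLDSeries", explainedVariance = "numeric",
                 nIterations = "integer", converged = "logical",
                 flatline = "logical", spec = "ModelSpec"))

setValidity("DCMPosterior", function(object) {
  if (!isTRUE(all.equal(object@cov, t(object@cov),
                        tolerance = 1e-8, check.attributes = FALSE)))
    return("posterior covariance must be symmetric")
  if (!is.finite(object@freeEnergy)) return("free energy must be finite")
  if (object@explainedVariance > 100 + 1e-8)
    return("explained variance cannot exceed 100%")
  TRUE
})

## ---------------------------------------------------------------------------
## Model spaces and group-level results
## ---------------------------------------------------------------------------

#' An enumerated space of DCM structures
#'
#' Stores one model per row of a compact integer code matrix: one column
#' per directed inter-regional edge with state 0 (absent), 1 (present) or
#' 2 (present + modulated), followed by one 0/1 column per region for the
#' driving input. [modelAt()] materialises row i as a [ModelSpec-class].
#' Enumeration order is lexicographic over the code columns, so model
#' indices are reproducible.
#'
#' @slot regionNames,nInputs shared structure of all models.
#' @slot edges 2-column integer matrix (target, source) listing the
#'   candidate directed edges in code-column order.
#' @slot codes n-by-(nEdges + l) integer matrix, one model per row.
#' @slot rule descriptor of the generation rule.
#' @slot variant,states passed through to materialised specs.
#' @slot familyLabels optional per-model family labels.
#' @seealso [enumerateFull()], [enumerateInputConstrained()], [modelAt()]
#' @exportClass ModelSpace
setClass("ModelSpace",
  representation(regionNames = "character", nInputs = "integer",
                 edges = "matrix", codes = "matrix", rule = "character",
                 variant = "character", states = "character",
                 familyLabels = "character"))

setValidity("ModelSpace", function(object) {
  nE <- nrow(object@edges)
  l <- length(object@regionNames)
  if (ncol(object@codes) != nE + l)
    return("code matrix must have one column per edge plus one per region")
  key <- paste(apply(object@codes, 1, paste, collapse = ""), object@variant)
  if (anyDuplicated(key)) return("models must be pairwise distinct")
  if (length(object@variant) != nrow(object@codes))
    return("need one variant per model")
  if (length(object@familyLabels) &&
      length(object@familyLabels) != nrow(object@codes))
    return("familyLabels must have one entry per model")
  TRUE
})

#' Random-effects Bayesian model selection result
#'
#' Posterior Dirichlet over model frequencies in the population, with
#' expected, exceedance and protected exceedance probabilities, and the
#' Bayesian omnibus risk (posterior probability that all model frequencies
#' are equal).
#'
#' @slot alpha posterior Dirichlet parameters (one per model).
#' @slot expected expected posterior model frequencies.
#' @slot exceedance probability each model is the most frequent.
#' @slot protectedExceedance exceedance shrunk toward chance by the BOR.
#' @slot bor Bayesian omnibus risk.
#' @slot modelNames labels.
#' @seealso [rfxInfer()]
#' @exportClass RFXResult
setClass("RFXResult",
  representation(alpha = "numeric", expected = "numeric",
                 exceedance = "numeric", protectedExceedance = "numeric",
                 bor = "numeric", modelNames = "character"))

setValidity("RFXResult", function(object) {
  for (nm in c("expected", "exceedance", "protectedExceedance")) {
    p <- slot(object, nm)
    if (abs(sum(p) - 1) > 1e-6)
      return(sprintf("%s must sum to 1", nm))
  }
  if (any(object@alpha <= 0)) return("alpha must be positive")
  if (object@bor < 0 || object@bor > 1) return("bor must lie in [0, 1]")
  TRUE
})

#' Connection-detection ROC curve
#'
#' @slot thresholds probability thresholds swept from strict to lenient.
#' @slot tpr,fpr true/false positive rates along the sweep (with the (0,0)
#'   and (1,1) endpoints included).
#' @slot auc trapezoidal area under the (fpr, tpr) path.
#' @seealso [connectionROC()]
#' @exportClass ROCResult
setClass("ROCResult",
  representation(thresholds = "numeric", tpr = "numeric", fpr = "numeric",
                 auc = "numeric"))

setValidity("ROCResult", function(object) {
  if (length(object@tpr) != length(object@fpr))
    return("tpr and fpr must align")
  if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
    return("tpr and fpr must be non-decreasing along the sweep")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  TRUE
})
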
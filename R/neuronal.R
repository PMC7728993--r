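## Neuronal state equations: bilinear and Wilson-Cowan, single- and
## two-state. Pure drift functions; the RK4 integrator and the inversion
## machinery consume these (an equivalent compiled path is used for speed,
## and is tested against these definitions).

#' Zero-centred sigmoid activation
#'
#' The Wilson-Cowan transfer function \eqn{S(x) = 1/(1 + e^{-\alpha x}) - 1/2},
#' an odd function of x bounded in (-1/2, 1/2). The shift by 1/2 puts the
#' resting fixed point at zero, so state variables are deviations from
#' baseline rather than total firing rates. Evaluated as
#' \code{tanh(alpha * x / 2) / 2}, which neither overflows nor loses the odd
#' symmetry for large \code{|alpha * x|}.
#'
#' @param x input (any numeric shape).
#' @param alpha sigmoid slope, strictly positive. Large alpha approaches a
#'   step; near the origin \eqn{S(x) \approx \alpha x / 4}, so
#'   \code{alpha = 4} gives unit small-signal gain.
#' @return S(x), same shape as \code{x}.
#' @examples
#' wcSigmoid(0.5, alpha = 4)      # 1/(1 + exp(-2)) - 1/2
#' wcSigmoid(1e6, alpha = 4)      # saturates at 1/2
#' @export
wcSigmoid <- function(x, alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("invalid parameter: alpha must be strictly positive")
  0.5 * tanh(0.5 * alpha * x)
}

.effectiveCoupling <- function(p, u) {
  A <- p@A
  for (j in seq_along(p@B)) if (u[j] != 0) A <- A + u[j] * p@B[[j]]
  A
}

#' Single-state neuronal drifts
#'
#' \code{bilinearDrift} evaluates the classical bilinear neuronal state
#' equation \eqn{\dot z = (A + \sum_j u_j B^j) z + C u}.
#' \code{wcDrift} evaluates its Wilson-Cowan replacement
#' \eqn{\dot z = -z + S(x)} with \eqn{x = (A + \sum_j u_j B^j) z + C u} and
#' the zero-centred sigmoid [wcSigmoid()] applied with region i's slope to
#' \eqn{x_i}. In the Wilson-Cowan form A, B and C are synaptic weights and
#' the sigmoid carries the local input-output nonlinearity, so the flow is
#' globally bounded: \eqn{\dot z + z \in (-1/2, 1/2)} component-wise, and
#' no input can destabilise the system.
#'
#' @param z numeric state vector, length l (deviation from baseline).
#' @param u numeric input vector, length m.
#' @param p a [NeuronalParams-class].
#' @return the drift \eqn{\dot z}, length l.
#' @examples
#' p <- neuronalParams(A = matrix(c(-1, 0.5, 0, -1), 2, 2),
#'                     C = matrix(c(1, 0), 2, 1), alpha = 4)
#' bilinearDrift(c(1, 0), 0, p)
#' wcDrift(c(1, 0), 0, p)
#' @export
bilinearDrift <- function(z, u, p) {
  l <- nrow(p@A)
  if (length(z) != l) stop("shape error: state length must equal nRegions")
  if (length(u) != ncol(p@Cin)) stop("shape error: input length must equal nInputs")
  drop(.effectiveCoupling(p, u) %*% z + p@Cin %*% u)
}

#' @rdname bilinearDrift
#' @export
wcDrift <- function(z, u, p) {
  l <- nrow(p@A)
  if (length(z) != l) stop("shape error: state length must equal nRegions")
  if (length(u) != ncol(p@Cin)) stop("shape error: input length must equal nInputs")
  x <- drop(.effectiveCoupling(p, u) %*% z + p@Cin %*% u)
  alpha <- rep_len(p@alpha, l)
  -z + 0.5 * tanh(0.5 * alpha * x)
}

.twoStateEffective <- function(p, u) {
  wEE <- p@wEE
  l <- nrow(wEE)
  bsum <- matrix(0, l, l)
  for (j in seq_along(p@bEE)) if (u[j] != 0) bsum <- bsum + u[j] * p@bEE[[j]]
  wEE <- wEE * exp(bsum)
  diag(wEE) <- 0
  wIE <- p@wIE
  esum <- numeric(l)
  for (j in seq_along(p@bIE)) if (u[j] != 0) esum <- esum + u[j] * p@bIE[[j]]
  list(wEE = wEE, wIE = wIE * exp(esum))
}

#' Two-state (excitatory/inhibitory) neuronal drifts
#'
#' Each region carries an excitatory state \code{zE} and an inhibitory state
#' \code{zI}. Inter-regional coupling is purely excitatory (\code{wEE}, one
#' weight per directed edge); within a region, E excites I (\code{wEI}),
#' I inhibits E (\code{wIE}), and each population has a self weight
#' (\code{wSE}, \code{wSI}). Driving inputs enter the excitatory state.
#' Modulatory inputs scale \code{wEE} and \code{wIE} multiplicatively
#' through \code{exp(b u)}, keeping the weights positive.
#'
#' \code{twoStateBilinearDrift} is the linear form:
#' \deqn{\dot z_E = W_{EE} z_E - w_{SE} z_E - w_{IE} z_I + C u, \quad
#'       \dot z_I = w_{EI} z_E - w_{SI} z_I.}
#' \code{twoStateWcDrift} is the Wilson-Cowan form
#' \eqn{\dot z = -z + S(x)} with
#' \deqn{x_E = W_{EE} z_E + w_{SE} z_E - w_{IE} z_I + C u, \quad
#'       x_I = w_{EI} z_E - w_{SI} z_I,}
#' and population-specific slopes \code{alphaE}, \code{alphaI}. Note the
#' sign of the self term differs between the two forms (decay in the linear
#' model, self-excitation inside the sigmoid argument in the Wilson-Cowan
#' model); both are written as printed in their defining equations.
#'
#' @param zE,zI excitatory and inhibitory state vectors, length l.
#' @param u input vector, length m.
#' @param p a [TwoStateParams-class].
#' @return list with components \code{E} and \code{I}: the two drifts.
#' @export
twoStateBilinearDrift <- function(zE, zI, u, p) {
  l <- nrow(p@wEE)
  if (length(zE) != l || length(zI) != l)
    stop("shape error: state length must equal nRegions")
  if (length(u) != ncol(p@Cin)) stop("shape error: input length must equal nInputs")
  w <- .twoStateEffective(p, u)
  dE <- drop(w$wEE %*% zE) - p@wSE * zE - w$wIE * zI + drop(p@Cin %*% u)
  dI <- p@wEI * zE - p@wSI * zI
  list(E = dE, I = dI)
}

#' @rdname twoStateBilinearDrift
#' @export
twoStateWcDrift <- function(zE, zI, u, p) {
  l <- nrow(p@wEE)
  if (length(zE) != l || length(zI) != l)
    stop("shape error: state length must equal nRegions")
  if (length(u) != ncol(p@Cin)) stop("shape error: input length must equal nInputs")
  w <- .twoStateEffective(p, u)
  xE <- drop(w$wEE %*% zE) + p@wSE * zE - w$wIE * zI + drop(p@Cin %*% u)
  xI <- p@wEI * zE - p@wSI * zI
  list(E = -zE + 0.5 * tanh(0.5 * p@alphaE * xE),
       I = -zI + 0.5 * tanh(0.5 * p@alphaI * xI))
}
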
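## Balloon/windkessel hemodynamics. Each region carries four states
## (s, f, v, q) downstream of its neuronal activity; resting point (0,1,1,1).

#' Balloon/windkessel hemodynamic state equation (one region)
#'
#' Drift of the four hemodynamic states driven by neuronal activity z:
#' vasodilatory signal s, normalized inflow f, normalized venous volume v,
#' and normalized deoxyhemoglobin content q,
#' \deqn{\dot s = z - \kappa s - \gamma (f - 1), \quad \dot f = s,}
#' \deqn{\dot v = (f - v^{1/\alpha_g}) / \tau_h, \quad
#'       \dot q = (f E(f, \rho)/\rho - v^{1/\alpha_g} q / v) / \tau_h,}
#' with oxygen extraction \eqn{E(f, \rho) = 1 - (1 - \rho)^{1/f}}. The
#' resting point is \code{(s, f, v, q) = (0, 1, 1, 1)}.
#'
#' @param h numeric length-4 state \code{c(s, f, v, q)}; f, v, q must be
#'   positive.
#' @param z neuronal activity driving the region (scalar).
#' @param p a [HemodynamicParams-class]; per-region vectors are indexed by
#'   \code{region}.
#' @param region which region's constants to use (default 1).
#' @return the length-4 drift \code{c(ds, df, dv, dq)}.
#' @examples
#' balloonDrift(c(0, 1, 1, 1), z = 0, hemodynamicParams())  # rest: all zero
#' @export
balloonDrift <- function(h, z, p, region = 1L) {
  if (length(h) != 4L) stop("state must be c(s, f, v, q)")
  s <- h[1]; f <- h[2]; v <- h[3]; q <- h[4]
  if (!is.finite(f) || !is.finite(v) || !is.finite(q) ||
      f <= 0 || v <= 0 || q <= 0)
    stop("state-domain error: f, v and q must be positive")
  kappa <- rep_len(p@kappa, region)[region]
  gamma <- rep_len(p@gamma, region)[region]
  tauH  <- rep_len(p@tauH, region)[region]
  E <- 1 - (1 - p@rho)^(1 / f)
  fout <- v^(1 / p@alphaG)
  c(z - kappa * s - gamma * (f - 1),
    s,
    (f - fout) / tauH,
    (f * E / p@rho - fout * q / v) / tauH)
}

#' BOLD observation equation
#'
#' Converts venous volume and deoxyhemoglobin content into percent BOLD
#' signal change:
#' \deqn{y = V_0 (k_1 (1 - q) + k_2 (1 - q/v) + k_3 (1 - v)).}
#' At rest (v = q = 1) the signal is zero. The equation yields fractional
#' signal change; the returned value is multiplied by 100 so that all
#' series in the package are in percent.
#'
#' @param h length-4 hemodynamic state \code{c(s, f, v, q)} (only v and q
#'   are used), or a length-2 vector \code{c(v, q)}.
#' @param p a [HemodynamicParams-class].
#' @return BOLD signal (% change), scalar.
#' @export
boldObserve <- function(h, p) {
  if (length(h) == 4L) { v <- h[3]; q <- h[4] }
  else if (length(h) == 2L) { v <- h[1]; q <- h[2] }
  else stop("state must be c(s, f, v, q) or c(v, q)")
  if (!is.finite(v) || !is.finite(q) || v <= 0 || q <= 0)
    stop("state-domain error: v and q must be positive")
  100 * p@V0 * (p@k1 * (1 - q) + p@k2 * (1 - q / v) + p@k3 * (1 - v))
}
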
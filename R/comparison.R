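## Group-level Bayesian model selection over free-energy evidence tables
## (subjects x models, nats): fixed effects (group Bayes factors), random
## effects (variational Dirichlet over model frequencies with exceedance
## and protected exceedance probabilities), family-level inference, and
## Bayesian model averaging.

.asEvidence <- function(F) {
  F <- as.matrix(F)
  if (!all(is.finite(F))) stop("evidence table must be finite")
  if (is.null(colnames(F))) colnames(F) <- paste0("M", seq_len(ncol(F)))
  F
}

.softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fixed-effects Bayesian model selection
#'
#' Treats all subjects as sharing one model: per-model group log-evidence
#' is the column sum of the free-energy table, posterior model
#' probabilities are its softmax (uniform model prior), and the pairwise
#' log group Bayes factors are the differences of the column sums. A log
#' Bayes factor of about 3 or more is conventionally "strong evidence",
#' reported in the \code{strong} matrix.
#'
#' @param F N-subjects-by-K-models matrix of free energies (nats); a
#'   vector is taken as a single subject.
#' @return list with \code{groupLogEvidence}, \code{posterior} (sums to
#'   1), \code{logGBF} (K-by-K, entry (i, j) favours i over j), and
#'   \code{strong} (logical, \code{logGBF >= 3}).
#' @examples
#' ffxCompare(rbind(c(3, 0)))$posterior  # ~ (0.9526, 0.0474)
#' @export
ffxCompare <- function(F) {
  if (is.vector(F)) F <- matrix(F, 1, dimnames = list(NULL, names(F)))
  F <- .asEvidence(F)
  gle <- colSums(F)
  post <- .softmax(gle)
  logGBF <- outer(gle, gle, `-`)
  list(groupLogEvidence = gle, posterior = post, logGBF = logGBF,
       strong = logGBF >= 3)
}

## variational Dirichlet scheme over model frequencies
.rfxVariational <- function(F, alpha0, maxIter = 1000L, tol = 1e-6) {
  N <- nrow(F)
  K <- ncol(F)
  alpha0 <- rep_len(alpha0, K)
  alpha <- alpha0 + N / K
  u <- matrix(1 / K, N, K)
  for (it in seq_len(maxIter)) {
    w <- sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- t(apply(w, 1, function(x) .softmax(x)))
    if (N == 1L) u <- matrix(u, 1, K)
    alphaNew <- alpha0 + colSums(u)
    if (max(abs(alphaNew - alpha)) < tol) { alpha <- alphaNew; break }
    alpha <- alphaNew
  }
  list(alpha = alpha, u = u, alpha0 = alpha0)
}

## free energy of the random-effects (alternative) frequency model
.rfxFreeEnergy <- function(F, fit) {
  lnB <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  u <- fit$u
  ent <- -sum(u[u > 0] * log(u[u > 0]))
  sum(u * F) + ent - lnB(fit$alpha0) + lnB(fit$alpha)
}

#' Exceedance probabilities of a Dirichlet density
#'
#' \eqn{\phi_k = \Pr(r_k = \max_j r_j)} under \eqn{r \sim Dir(\alpha)},
#' estimated by seeded Monte-Carlo sampling (for K = 2 this equals the
#' regularized incomplete beta function \eqn{\Pr(Beta(\alpha_1, \alpha_2)
#' > 1/2)}, which tests use as the closed-form cross-check).
#'
#' @param alpha positive Dirichlet parameters.
#' @param nSamples Monte-Carlo sample count (default 1e5).
#' @param seed integer seed.
#' @return probability vector summing to 1.
#' @export
exceedanceProb <- function(alpha, nSamples = 1e5, seed = 1L) {
  stopifnot(all(alpha > 0))
  K <- length(alpha)
  if (K == 1L) return(1)
  set.seed(as.integer(seed))
  ## Dirichlet via normalized gammas; only the argmax matters
  g <- matrix(stats::rgamma(nSamples * K, shape = rep(alpha, each = nSamples)),
              nSamples, K)
  idx <- max.col(g, ties.method = "first")
  tabulate(idx, K) / nSamples
}

#' Protected exceedance probabilities and the Bayesian omnibus risk
#'
#' The exceedance probability does not consider the null hypothesis that
#' all models are equally frequent in the population. The Bayesian omnibus
#' risk (BOR) is the posterior probability of that null, computed from the
#' free energies of the null model (frequencies fixed at 1/K) and of the
#' random-effects alternative; the protected exceedance probability shrinks
#' toward chance accordingly:
#' \deqn{\tilde\phi_k = \phi_k (1 - BOR) + BOR / K.}
#'
#' @param exceedance exceedance probability vector.
#' @param F the subjects-by-models evidence table the exceedance was
#'   computed from.
#' @param alpha0 Dirichlet prior parameters (default 1 per model).
#' @return list with \code{protected} and \code{bor}.
#' @export
protectExceedance <- function(exceedance, F, alpha0 = 1) {
  F <- .asEvidence(F)
  K <- ncol(F)
  stopifnot(length(exceedance) == K)
  fit <- .rfxVariational(F, alpha0)
  F1 <- .rfxFreeEnergy(F, fit)
  F0 <- sum(apply(F, 1, function(f) .logsumexp(f - log(K))))
  bor <- 1 / (1 + exp(F1 - F0))
  list(protected = exceedance * (1 - bor) + bor / K, bor = bor)
}

#' Random-effects Bayesian model selection
#'
#' Hierarchical (random-effects) group inference: model frequencies in the
#' population carry a Dirichlet prior, and subject-wise model assignments
#' are updated variationally against the Dirichlet posterior
#' (\eqn{u_{nk} \propto \exp(F_{nk} + \psi(\alpha_k) - \psi(\sum
#' \alpha))}) until the alpha change falls below \code{1e-6}. Reports
#' expected frequencies \eqn{\alpha/\sum\alpha}, Monte-Carlo exceedance
#' probabilities, and protected exceedance probabilities via the Bayesian
#' omnibus risk.
#'
#' @param F N-by-K evidence table (nats).
#' @param alpha0 Dirichlet prior (default 1 per model, flat).
#' @param nSamples Monte-Carlo samples for the exceedance estimate.
#' @param seed integer seed for the exceedance sampling.
#' @return An [RFXResult-class].
#' @export
rfxInfer <- function(F, alpha0 = 1, nSamples = 1e5, seed = 1L) {
  F <- .asEvidence(F)
  fit <- .rfxVariational(F, alpha0)
  phi <- exceedanceProb(fit$alpha, nSamples = nSamples, seed = seed)
  prot <- protectExceedance(phi, F, alpha0 = alpha0)
  new("RFXResult", alpha = fit$alpha, expected = fit$alpha / sum(fit$alpha),
      exceedance = phi, protectedExceedance = prot$protected,
      bor = prot$bor, modelNames = colnames(F))
}

#' Family-level Bayesian model selection
#'
#' Compares groups (families) of models rather than single models, with
#' the model prior re-normalized so that every family carries equal prior
#' mass regardless of its size (uniform within family).
#'
#' FFX: family posterior = sum of member posteriors under the corrected
#' prior. RFX: each family is treated as one mixture model whose
#' per-subject evidence is the log-mean-exp of its members' free energies
#' (uniform within-family prior), and the Dirichlet scheme is run over
#' families; with identical evidence everywhere this correctly returns
#' chance-level family probabilities regardless of family sizes.
#'
#' @param F N-by-K evidence table (nats).
#' @param families family label per model (character vector of length K,
#'   or a [ModelSpace-class] whose \code{familyLabels} are set).
#' @param mode \code{"ffx"} or \code{"rfx"}.
#' @param nSamples,seed Monte-Carlo controls for RFX exceedance.
#' @return For FFX: named family posterior probabilities. For RFX: list
#'   with \code{expected}, \code{exceedance}, \code{alpha} (all per
#'   family).
#' @export
familyLevel <- function(F, families, mode = c("ffx", "rfx"),
                        nSamples = 1e5, seed = 1L) {
  mode <- match.arg(mode)
  F <- .asEvidence(F)
  if (is(families, "ModelSpace")) families <- familyLabels(families)
  families <- as.character(families)
  if (length(families) != ncol(F))
    stop("need one family label per model")
  fam <- unique(families)
  if (any(!nzchar(fam))) stop("empty family label")
  sizes <- table(factor(families, levels = fam))
  if (mode == "ffx") {
    logPrior <- -log(length(fam)) - log(as.numeric(sizes[families]))
    lp <- colSums(F) + logPrior
    post <- .softmax(lp)
    tapply(post, factor(families, levels = fam), sum)
  } else {
    ## per-subject family evidence: log-mean-exp over member models
    Ffam <- vapply(fam, function(f) {
      cols <- F[, families == f, drop = FALSE]
      apply(cols, 1, function(x) .logsumexp(x - log(length(x))))
    }, numeric(nrow(F)))
    if (nrow(F) == 1L) Ffam <- matrix(Ffam, 1, dimnames = list(NULL, fam))
    fit <- .rfxVariational(Ffam, 1)
    list(expected = setNames(fit$alpha / sum(fit$alpha), fam),
         exceedance = setNames(
           exceedanceProb(fit$alpha, nSamples = nSamples, seed = seed), fam),
         alpha = setNames(fit$alpha, fam))
  }
}

#' Bayesian model averaging of connectivity parameters
#'
#' Averages each parameter over models weighted by the posterior model
#' probabilities: \eqn{\bar\theta = \sum_m p(m) \mu_m}. A model that does
#' not contain a parameter contributes value 0 with all probability mass
#' at 0. The sign probability of a parameter is the model-averaged
#' posterior confidence in its sign,
#' \eqn{\sum_m p(m) \max(\Pr(\theta > 0 | m), \Pr(\theta < 0 | m))}, and a
#' parameter is flagged significant when it exceeds \code{threshold}.
#'
#' @param posteriors list of fitted models: [DCMPosterior-class] objects,
#'   or lists with named numeric components \code{mean} and \code{sd}.
#' @param probabilities posterior model probabilities (must sum to 1).
#' @param threshold significance threshold on the sign probability
#'   (default 0.95).
#' @return data.frame with columns \code{parameter}, \code{mean},
#'   \code{signProb}, \code{significant}.
#' @export
bma <- function(posteriors, probabilities, threshold = 0.95) {
  if (abs(sum(probabilities) - 1) > 1e-6)
    stop("model probabilities must sum to 1")
  if (length(posteriors) != length(probabilities))
    stop("need one probability per model")
  summaries <- lapply(posteriors, function(p) {
    if (is(p, "DCMPosterior"))
      list(mean = p@mean, sd = sqrt(pmax(diag(p@cov), 0)))
    else list(mean = p$mean, sd = p$sd)
  })
  pars <- unique(unlist(lapply(summaries, function(s) names(s$mean))))
  mu <- sp <- setNames(numeric(length(pars)), pars)
  for (m in seq_along(summaries)) {
    s <- summaries[[m]]
    pm <- probabilities[m]
    for (nm in names(s$mean)) {
      mu[nm] <- mu[nm] + pm * s$mean[[nm]]
      conf <- if (s$sd[[nm]] > 0) {
        z <- s$mean[[nm]] / s$sd[[nm]]
        max(pnorm(z), pnorm(-z))
      } else as.numeric(s$mean[[nm]] != 0)  # point mass: certain sign unless at 0
      sp[nm] <- sp[nm] + pm * conf
    }
  }
  data.frame(parameter = pars, mean = unname(mu), signProb = unname(sp),
             significant = unname(sp > threshold),
             stringsAsFactors = FALSE)
}
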
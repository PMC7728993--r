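test_that("fixed-effects comparison follows the softmax closed form", {
  ## one subject, dF = 3 nats: BF = e^3, posterior (0.9526, 0.0474)
  res <- ffxCompare(rbind(c(3, 0)))
  expect_equal(exp(res$logGBF[1, 2]), exp(3), tolerance = 1e-12)
  expect_equal(unname(res$posterior), c(0.9526, 0.0474), tolerance = 1e-3)
  expect_true(res$strong[1, 2])
  expect_false(res$strong[2, 1])
  ## equal evidence: uniform posterior
  resEq <- ffxCompare(matrix(1.7, 5, 4))
  expect_equal(unname(resEq$posterior), rep(0.25, 4))
  ## permutation equivariance and normalisation
  set.seed(12)
  F <- matrix(rnorm(30), 6, 5)
  perm <- sample(5)
  expect_equal(sum(ffxCompare(F)$posterior), 1)
  expect_equal(unname(ffxCompare(F[, perm])$posterior),
               unname(ffxCompare(F)$posterior[perm]))
})

test_that("random-effects inference matches an independent variational iteration", {
  ## independent implementation of the Dirichlet scheme, written as the
  ## update equations read
  refRfx <- function(F, a0 = 1) {
    K <- ncol(F); alpha <- rep(a0, K) + nrow(F) / K
    for (it in 1:2000) {
      w <- sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
      u <- exp(w - apply(w, 1, max))
      u <- u / rowSums(u)
      aNew <- rep(a0, K) + colSums(u)
      if (max(abs(aNew - alpha)) < 1e-10) { alpha <- aNew; break }
      alpha <- aNew
    }
    alpha
  }
  ## every one of 10 subjects favours model 1 by 5 nats
  F <- matrix(c(rep(5, 10), rep(0, 10)), 10, 2)
  fit <- rfxInfer(F, seed = 1)
  expect_equal(unname(fit@alpha), refRfx(F), tolerance = 1e-4)
  expect_equal(unname(fit@alpha), c(11, 1), tolerance = 0.05)
  expect_equal(unname(fit@expected), c(11, 1) / 12, tolerance = 0.01)
  expect_gt(fit@exceedance[1], 0.99)
  ## identical evidence: symmetric result
  fitEq <- rfxInfer(matrix(2, 8, 3), seed = 2)
  expect_equal(unname(fitEq@expected), rep(1 / 3, 3), tolerance = 1e-6)
  expect_equal(fitEq@exceedance, rep(1 / 3, 3), tolerance = 0.02)
  expect_equal(sum(fitEq@exceedance), 1, tolerance = 1e-9)
  expect_error(rfxInfer(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("Monte-Carlo exceedance matches the incomplete-beta closed form", {
  expect_equal(exceedanceProb(c(1, 1), seed = 3), c(0.5, 0.5),
               tolerance = 0.01)
  ## K = 2: phi_1 = Pr(Beta(8, 4) > 1/2)
  phi <- exceedanceProb(c(8, 4), nSamples = 1e6, seed = 5)
  expect_equal(phi[1], 1 - pbeta(0.5, 8, 4), tolerance = 1e-3)
  expect_equal(sum(phi), 1)
  ## permutation equivariance (same seed, permuted parameters)
  a <- c(3, 7, 2)
  p1 <- exceedanceProb(a, nSamples = 2e5, seed = 9)
  p2 <- exceedanceProb(a[c(2, 1, 3)], nSamples = 2e5, seed = 10)
  expect_equal(p1[c(2, 1, 3)], p2, tolerance = 0.01)
})

test_that("protected exceedance interpolates between evidence and chance", {
  ## strong unanimous evidence: BOR small, protected ~ exceedance
  Fstrong <- matrix(c(rep(5, 20), rep(0, 20)), 20, 2)
  fit <- rfxInfer(Fstrong, seed = 7)
  expect_lt(fit@bor, 0.05)
  expect_gt(fit@protectedExceedance[1], 0.95)
  ## the defining identity phi~ = phi (1 - BOR) + BOR / K holds exactly
  expect_equal(fit@protectedExceedance,
               fit@exceedance * (1 - fit@bor) + fit@bor / 2, tolerance = 1e-12)
  ## no information: the null keeps most of the mass, protected ~ chance
  fit0 <- rfxInfer(matrix(0, 12, 3), seed = 8)
  expect_gt(fit0@bor, 0.5)
  expect_equal(unname(fit0@protectedExceedance), rep(1 / 3, 3),
               tolerance = 0.05)
})

test_that("family-level inference equalises prior mass across families", {
  ## unequal family sizes, identical evidence: posterior (0.5, 0.5)
  F <- matrix(0, 6, 3)
  colnames(F) <- c("a1", "a2", "b1")
  fams <- c("A", "A", "B")
  post <- familyLevel(F, fams, mode = "ffx")
  expect_equal(unname(as.numeric(post)), c(0.5, 0.5), tolerance = 1e-12)
  ## family A's models each lead by 3 nats per subject: A wins decisively
  F2 <- cbind(a1 = rep(3, 1), a2 = rep(3, 1), b1 = 0, b2 = 0)
  expect_gt(familyLevel(F2, c("A", "A", "B", "B"), mode = "ffx")[["A"]], 0.95)
  ## single family gets probability one
  expect_equal(unname(as.numeric(familyLevel(F, rep("A", 3), "ffx"))), 1)
  ## RFX mode: symmetric case stays symmetric despite unequal sizes
  rfx <- familyLevel(matrix(0, 10, 3), fams, mode = "rfx", seed = 3)
  expect_equal(unname(as.numeric(rfx$expected)), c(0.5, 0.5), tolerance = 0.02)
  expect_equal(sum(rfx$exceedance), 1, tolerance = 1e-9)
  expect_error(familyLevel(F, c("A", "A")), "one family label")
})

test_that("model averaging weights means and sign confidence by model probability", {
  p1 <- list(mean = c(x = 0.2, y = 1), sd = c(x = 0.1, y = 0.5))
  p2 <- list(mean = c(x = 0.4), sd = c(x = 0.1))
  ## single model: identity
  one <- bma(list(p1), 1)
  expect_equal(one$mean[one$parameter == "x"], 0.2)
  ## two models at 0.5/0.5: mean of means; y absent from model 2
  avg <- bma(list(p1, p2), c(0.5, 0.5))
  expect_equal(avg$mean[avg$parameter == "x"], 0.3)
  expect_equal(avg$mean[avg$parameter == "y"], 0.5)
  ## mean at 1.645 sd: sign probability 0.95
  g <- list(mean = c(w = 1.645 * 0.2), sd = c(w = 0.2))
  res <- bma(list(g), 1)
  expect_equal(res$signProb, 0.95, tolerance = 1e-3)
  expect_error(bma(list(p1, p2), c(0.7, 0.7)), "sum to 1")
})
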
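gtWc <- groundTruthNetwork("wilson_cowan")
inp <- standardInputs()

test_that("default priors pin masked-out parameters and count 21 free parameters", {
  pr <- defaultPriors(gtWc$spec)
  lay <- dcmWC:::.paramLayout(gtWc$spec)
  ## 3 self + 3 edges + 2 modulations + 1 input + 3 slopes + 6 hemodynamic
  ## scalings + 3 noise log-precisions
  expect_equal(nFreeParams(pr), 21)
  ## no free parameter exists outside the structural masks
  Aoff <- lay[lay$group == "A" & lay$i != lay$j, ]
  expect_setequal(sprintf("%d<-%d", Aoff$i, Aoff$j),
                  c("2<-1", "3<-1", "2<-3"))
  expect_false(any(lay$group == "B" & lay$k == 1))  # input 1 modulates nothing
  ## shrinkage: every allowed off-diagonal coupling has prior mean 0
  expect_true(all(pr@mean[Aoff$name] == 0))
  expect_true(all(pr@mean[lay$name[lay$group == "B"]] == 0))
  expect_true(all(pr@variance > 0))
  ## diagonal prior is the tight classical self-connection prior
  Adiag <- lay[lay$group == "A" & lay$i == lay$j, ]
  expect_true(all(pr@mean[Adiag$name] == -0.5))
  expect_true(all(pr@variance[Adiag$name] == 1 / 256))
  ## shared-alpha option collapses the slopes to one parameter
  expect_equal(nFreeParams(defaultPriors(gtWc$spec, sharedAlpha = TRUE)), 19)
})

test_that("free energy components behave as Gaussian algebra dictates", {
  N <- 50
  resid <- matrix(0, N, 1)
  lambda <- exp(2.5)
  ## zero residuals, fixed precision: accuracy is (N/2)(ln lambda - ln 2 pi)
  expect_equal(freeEnergyVBL(resid, hMean = 2.5),
               (N / 2) * (2.5 - log(2 * pi)), tolerance = 1e-12)
  ## posterior identical to prior: parameter complexity is exactly zero
  mu <- c(0.3, -0.2); V <- diag(c(0.1, 0.2))
  fSame <- freeEnergyVBL(resid, 2.5, postMean = mu, postCov = V,
                         priorMean = mu, priorCov = V)
  expect_equal(fSame, (N / 2) * (2.5 - log(2 * pi)), tolerance = 1e-10)
  ## doubling the residuals strictly decreases F
  set.seed(2)
  r1 <- matrix(rnorm(N), N, 1)
  expect_lt(freeEnergyVBL(2 * r1, 2.5), freeEnergyVBL(r1, 2.5))
  ## a posterior different from the prior costs complexity
  fDiff <- freeEnergyVBL(resid, 2.5, postMean = mu + 1, postCov = V,
                         priorMean = mu, priorCov = V)
  expect_lt(fDiff, fSame)
})

test_that("explained variance follows the variance decomposition", {
  set.seed(9)
  obs <- matrix(rnorm(600), 200, 3)
  expect_equal(explainedVariance(obs, obs), 100)
  means <- matrix(colMeans(obs), 200, 3, byrow = TRUE)
  expect_equal(explainedVariance(obs, means), 0, tolerance = 1e-10)
  ## orthogonal noise with var(noise) = var(pred)/3 gives exactly 75%
  pred <- matrix(rnorm(600), 200, 3)
  pred <- scale(pred, scale = FALSE)
  noise <- matrix(rnorm(600), 200, 3)
  noise <- scale(noise, scale = FALSE)
  ## orthogonalise noise against pred, then rescale pooled variances
  noise <- noise - pred * sum(noise * pred) / sum(pred * pred)
  noise <- noise * sqrt(sum(pred^2) / 3 / sum(noise^2))
  expect_equal(explainedVariance(pred + noise, pred), 75, tolerance = 1e-6)
  expect_error(explainedVariance(matrix(1, 10, 2), matrix(1, 10, 2)),
               "zero variance")
  expect_error(explainedVariance(obs, obs[1:10, ]), "shape")
})

test_that("flat-line detection uses a strict variance-ratio threshold", {
  obs <- boldSeries(matrix(rnorm(300), 100, 3), TR = 2)
  flat <- boldSeries(matrix(5, 100, 3), TR = 2)
  expect_true(detectFlatline(flat, obs))
  expect_false(detectFlatline(obs, obs))
  ## exactly at the threshold: strict inequality, so not flagged
  y <- matrix(rep(c(-1, 1), 50), 100, 1)  # exact dyadic variances
  pred <- y * 2^-5
  expect_false(detectFlatline(pred, y, tol = 2^-10))
  expect_true(detectFlatline(pred * 0.5, y, tol = 2^-10))
})

test_that("noise-free Wilson-Cowan data are recovered to tight tolerances", {
  sim <- integrateDCM(gtWc$spec, gtWc$neuronal, inputs = inp, TR = 2)
  post <- invertDCM(sim$bold, inp, gtWc$spec)
  ## free energy never decreases across accepted iterations
  expect_true(all(diff(post@Ftrajectory) >= -1e-9))
  expect_gt(explainedVarianceOf(post), 99)
  expect_false(isFlatline(post))
  rec <- recoveryMetrics(gtWc$neuronal, post)
  expect_gt(rec$correlation, 0.9)
  ## every nonzero coupling within 3 posterior standard deviations of truth
  sds <- sqrt(diag(posteriorCov(post))[rec$table$parameter])
  expect_true(all(abs(rec$table$bias) <= 3 * sds + 1e-8))
})

test_that("a structurally wrong model attains lower evidence at high SNR", {
  sim <- integrateDCM(gtWc$spec, gtWc$neuronal, inputs = inp, TR = 2)
  fTrue <- freeEnergy(invertDCM(sim$bold, inp, gtWc$spec))
  ## wrong structure: reversed edges, modulation on the wrong connection
  Am <- diag(3) == 1
  Am[1, 2] <- Am[1, 3] <- Am[3, 2] <- TRUE
  Bm <- matrix(FALSE, 3, 3); Bm[1, 2] <- TRUE
  wrong <- modelSpec(c("R1", "R2", "R3"), Am,
                     Bmasks = list(matrix(FALSE, 3, 3), Bm),
                     drivingMask(gtWc$spec), variant = "wilson_cowan")
  fWrong <- freeEnergy(invertDCM(sim$bold, inp, wrong))
  expect_gt(fTrue, fWrong)
})

test_that("a two-state Wilson-Cowan model can be inverted end to end", {
  spec2 <- modelSpec(c("R1", "R2"),
                     Amask = matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2),
                     Bmasks = matrix(FALSE, 2, 2),
                     Cmask = matrix(c(TRUE, FALSE), 2, 1),
                     variant = "wilson_cowan", states = "two")
  np2 <- twoStateParams(wEE = matrix(c(0, 0.4, 0, 0), 2, 2),
                        C = matrix(c(0.5, 0), 2, 1))
  dt <- 0.125
  u <- matrix(as.numeric(seq(0, 240 - dt, dt) %% 40 >= 20), 1)
  inp2 <- inputTimeline(u, dt = dt)
  sim <- integrateDCM(spec2, np2, inputs = inp2, TR = 2)
  post <- invertDCM(sim$bold, inp2, spec2, opts = list(maxIter = 12))
  expect_s4_class(post, "DCMPosterior")
  expect_true(all(diff(post@Ftrajectory) >= -1e-9))
  expect_gt(explainedVarianceOf(post), 50)
})

test_that("posterior sign probabilities separate real from absent couplings", {
  sim <- integrateDCM(gtWc$spec, gtWc$neuronal, inputs = inp, TR = 2)
  sat <- dcmWC:::.saturatedSpec(gtWc$spec, "wilson_cowan")
  post <- invertDCM(sim$bold, inp, sat)
  sc <- connectionScores(post)
  present <- c("2<-1", "3<-1", "2<-3")
  absent <- setdiff(names(sc), present)
  expect_gt(min(sc[present]), max(0.5, mean(sc[absent]) - 0.5))
  expect_true(all(sc >= 0.5 & sc <= 1))
})
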
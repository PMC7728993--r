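test_that("the resting cascade produces an identically zero BOLD signal", {
  gt <- groundTruthNetwork()
  inp <- standardInputs(duration = 120)
  ## zero out the driving input: nothing ever leaves the fixed point
  silent <- neuronalParams(gt$neuronal@A, gt$neuronal@B,
                           matrix(0, 3, 2), alpha = 4)
  out <- integrateDCM(gt$spec, silent, inputs = inp, TR = 2)
  expect_equal(max(abs(boldMatrix(out$bold))), 0)
})

test_that("latent dynamics match the closed-form linear solution", {
  ## single region, ż = a z + c u with constant u = 1:
  ## z(t) = (c/-a) (1 - exp(a t))
  a <- -0.8; cc <- 0.5
  sp <- modelSpec("R1", matrix(TRUE, 1, 1), matrix(FALSE, 1, 1),
                  matrix(TRUE, 1, 1), variant = "bilinear")
  np <- neuronalParams(matrix(a, 1, 1), C = matrix(cc, 1, 1))
  dt <- 0.125
  inp <- inputTimeline(matrix(1, 1, 120 / dt), dt = dt)
  out <- integrateDCM(sp, np, inputs = inp, TR = 2, keepLatent = TRUE)
  tSamp <- 2 * seq_len(nrow(out$latent))
  expect_equal(out$latent[, 1], (cc / -a) * (1 - exp(a * tSamp)),
               tolerance = 1e-6)
})

test_that("halving the integration step leaves the sampled BOLD unchanged to 1e-6", {
  for (v in c("bilinear", "wilson_cowan")) {
    gt <- groundTruthNetwork(v)
    inp <- standardInputs(duration = 240, dt = 2 / 16)
    y1 <- boldMatrix(integrateDCM(gt$spec, gt$neuronal, inputs = inp,
                                  TR = 2)$bold)
    y2 <- boldMatrix(integrateDCM(gt$spec, gt$neuronal, inputs = inp,
                                  TR = 2, dt = 2 / 32)$bold)
    expect_lt(sqrt(mean((y1 - y2)^2)), 1e-6)
  }
})

test_that("the compiled integrator agrees with a plain-R RK4 reference", {
  for (v in c("bilinear", "wilson_cowan")) {
    gt <- groundTruthNetwork(v)
    inp <- standardInputs(duration = 120)
    y <- boldMatrix(integrateDCM(gt$spec, gt$neuronal, inputs = inp,
                                 TR = 2)$bold)
    yRef <- oracleIntegrate(gt$spec, gt$neuronal, hemodynamicParams(),
                            inp, TR = 2)
    expect_equal(y, yRef, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("the ground-truth network has exactly the published structure", {
  gt <- groundTruthNetwork()
  Am <- connectionMask(gt$spec)
  offdiag <- which(Am & !diag(3), arr.ind = TRUE)
  expect_setequal(sprintf("%d<-%d", offdiag[, 1], offdiag[, 2]),
                  c("2<-1", "3<-1", "2<-3"))
  Bm <- modulationMasks(gt$spec)
  expect_false(any(Bm[[1]]))
  modulated <- which(Bm[[2]], arr.ind = TRUE)
  expect_setequal(sprintf("%d<-%d", modulated[, 1], modulated[, 2]),
                  c("3<-1", "2<-3"))
  Cm <- drivingMask(gt$spec)
  expect_equal(which(Cm), 1L)  # input 1 into region 1 only
})

test_that("synthetic noise honours the SNR definition and the seeding contract", {
  gt <- groundTruthNetwork()
  inp <- standardInputs(duration = 720)
  ## snr = Inf returns the clean series
  dInf <- simulateDataset(gt$spec, gt$neuronal, inputs = inp, snr = Inf,
                          nReal = 2, seed = 1)
  expect_identical(boldMatrix(dInf@noisy[[1]]), boldMatrix(dInf@clean))
  ## empirical sd(noise)/sd(clean) = 1/snr within 10% (360 samples, pooled
  ## over 10 realizations)
  ds <- simulateDataset(gt$spec, gt$neuronal, inputs = inp, snr = 2,
                        nReal = 10, seed = 3)
  clean <- boldMatrix(ds@clean)
  for (region in 1:3) {
    resid <- unlist(lapply(ds@noisy, function(b)
      boldMatrix(b)[, region] - clean[, region]))
    expect_equal(sd(resid) / sd(clean[, region]), 1 / 2, tolerance = 0.1)
  }
  ## reproducibility
  again <- simulateDataset(gt$spec, gt$neuronal, inputs = inp, snr = 2,
                           nReal = 10, seed = 3)
  expect_identical(boldMatrix(again@noisy[[5]]), boldMatrix(ds@noisy[[5]]))
  other <- simulateDataset(gt$spec, gt$neuronal, inputs = inp, snr = 2,
                           nReal = 1, seed = 4)
  expect_false(identical(boldMatrix(other@noisy[[1]]),
                         boldMatrix(ds@noisy[[1]])))
  expect_error(simulateDataset(gt$spec, gt$neuronal, inputs = inp, snr = 0,
                               nReal = 1, seed = 1), "snr")
})

test_that("simulation commutes with restriction to a decoupled subnetwork", {
  ## 3-region model whose region 3 is fully decoupled equals the 2-region
  ## model on the shared regions
  A3 <- matrix(0, 3, 3); diag(A3) <- -0.5; A3[2, 1] <- 0.4
  C3 <- matrix(0, 3, 1); C3[1, 1] <- 0.6
  sp3 <- modelSpec(c("R1", "R2", "R3"), A3 != 0 | diag(3) == 1,
                   matrix(FALSE, 3, 3), C3 != 0, variant = "wilson_cowan")
  A2 <- A3[1:2, 1:2]; C2 <- C3[1:2, , drop = FALSE]
  sp2 <- modelSpec(c("R1", "R2"), A2 != 0 | diag(2) == 1,
                   matrix(FALSE, 2, 2), C2 != 0, variant = "wilson_cowan")
  dt <- 0.125
  inp <- inputTimeline(matrix(as.numeric(seq(0, 120 - dt, dt) %% 40 >= 20),
                              1), dt = dt)
  y3 <- boldMatrix(integrateDCM(sp3, neuronalParams(A3, C = C3, alpha = 4),
                                inputs = inp, TR = 2)$bold)
  y2 <- boldMatrix(integrateDCM(sp2, neuronalParams(A2, C = C2, alpha = 4),
                                inputs = inp, TR = 2)$bold)
  expect_equal(y3[, 1:2], y2, ignore_attr = TRUE)
  expect_equal(max(abs(y3[, 3])), 0)
})

test_that("Wilson-Cowan runs stay finite where bilinear runs diverge", {
  set.seed(21)
  inp <- standardInputs(duration = 120)
  for (rep in 1:10) {
    A <- matrix(runif(9, -2, 2), 3, 3)
    gt <- groundTruthNetwork()
    spWc <- modelSpec(c("R1", "R2", "R3"), matrix(TRUE, 3, 3),
                      modulationMasks(gt$spec), drivingMask(gt$spec),
                      variant = "wilson_cowan")
    np <- neuronalParams(A, B = gt$neuronal@B, C = gt$neuronal@Cin, alpha = 4)
    expect_no_error(integrateDCM(spWc, np, inputs = inp, TR = 2))
  }
  ## a bilinear system with an unstable coupling surfaces a divergence error
  Abad <- matrix(c(0.5, 0, 0, -0.5), 2, 2)
  spB <- modelSpec(c("R1", "R2"), matrix(TRUE, 2, 2), matrix(FALSE, 2, 2),
                   matrix(c(TRUE, FALSE), 2, 1), variant = "bilinear")
  npB <- neuronalParams(Abad, C = matrix(c(1, 0), 2, 1))
  inp1 <- inputTimeline(matrix(1, 1, 120 / 0.125), dt = 0.125)
  err <- tryCatch(integrateDCM(spB, npB, inputs = inp1, TR = 2),
                  dcmDivergenceError = function(e) e)
  expect_s3_class(err, "dcmDivergenceError")
  expect_true(err$step >= 1)
})
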
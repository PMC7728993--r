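test_that("wcSigmoid matches its defining formula and is numerically stable", {
  expect_identical(wcSigmoid(0, 4), 0)
  expect_equal(wcSigmoid(0.5, 4), 1 / (1 + exp(-2)) - 0.5, tolerance = 1e-12)
  expect_equal(wcSigmoid(0.5, 4), 0.3807970779778823, tolerance = 1e-12)
  ## saturation without overflow even at |alpha x| = 1e3
  expect_equal(wcSigmoid(250, 4), 0.5)
  expect_equal(wcSigmoid(-250, 4), -0.5)
  expect_true(all(is.finite(wcSigmoid(c(-1e6, 1e6), 4))))
  ## bounded and odd
  xs <- seq(-20, 20, length.out = 101)
  expect_true(all(abs(wcSigmoid(xs, 2)) <= 0.5))
  expect_equal(wcSigmoid(-xs, 3), -wcSigmoid(xs, 3))
  expect_error(wcSigmoid(1, 0), "alpha")
  expect_error(wcSigmoid(1, -2), "alpha")
})

test_that("bilinear drift reproduces hand calculations and rejects bad shapes", {
  p <- neuronalParams(A = matrix(c(-1, 0.5, 0, -1), 2, 2),
                      C = matrix(0, 2, 1))
  expect_equal(bilinearDrift(c(0, 0), 0, p), c(0, 0))
  expect_equal(bilinearDrift(c(1, 0), 0, p), c(-1, 0.5))
  expect_error(bilinearDrift(c(1, 0, 0), 0, p), "shape")
  expect_error(bilinearDrift(c(1, 0), c(0, 0), p), "shape")
})

test_that("all four drifts agree with naive loop oracles to 1e-12", {
  set.seed(42)
  for (rep in 1:25) {
    s <- randomSingleInstance(l = sample(2:4, 1))
    expect_equal(bilinearDrift(s$z, s$u, s$p),
                 oracleBilinear(s$z, s$u, s$A, s$B, s$C), tolerance = 1e-12)
    expect_equal(wcDrift(s$z, s$u, s$p),
                 oracleWc(s$z, s$u, s$A, s$B, s$C, s$alpha), tolerance = 1e-12)
    t2 <- randomTwoStateInstance(l = sample(2:4, 1))
    expect_equal(
      twoStateBilinearDrift(t2$zE, t2$zI, t2$u, t2$p),
      oracleTwoBilinear(t2$zE, t2$zI, t2$u, t2$wEE, t2$bEE, t2$wSE, t2$wSI,
                        t2$wIE, t2$wEI, t2$bIE, t2$C), tolerance = 1e-12)
    expect_equal(
      twoStateWcDrift(t2$zE, t2$zI, t2$u, t2$p),
      oracleTwoWc(t2$zE, t2$zI, t2$u, t2$wEE, t2$bEE, t2$wSE, t2$wSI,
                  t2$wIE, t2$wEI, t2$bIE, t2$C, t2$alphaE, t2$alphaI),
      tolerance = 1e-12)
  }
})

test_that("Wilson-Cowan flow is bounded, odd, and fixed at the origin", {
  set.seed(7)
  s <- randomSingleInstance()
  l <- length(s$z)
  expect_equal(wcDrift(rep(0, l), rep(0, 2), s$p), rep(0, l))
  ## drift + z = S(x) stays inside (-1/2, 1/2) whatever the state or input
  for (rep in 1:20) {
    z <- rnorm(l, sd = 5); u <- rnorm(2, sd = 5)
    expect_true(all(abs(wcDrift(z, u, s$p) + z) <= 0.5))
  }
  ## odd symmetry when the driving term vanishes
  p0 <- neuronalParams(s$A, s$B, matrix(0, l, 2), alpha = s$alpha)
  z <- rnorm(l)
  expect_equal(wcDrift(-z, c(0, 0), p0), -wcDrift(z, c(0, 0), p0))
})

test_that("two-state drifts honour their defining sign structure", {
  ## single region, wEI = 0: the inhibitory state purely decays
  p <- twoStateParams(wEE = matrix(0, 1, 1), wSE = 0.4, wSI = 0.7,
                      wIE = 0.3, wEI = 0, C = matrix(0, 1, 1))
  expect_equal(twoStateBilinearDrift(0, 0, 0, p), list(E = 0, I = 0))
  d <- twoStateBilinearDrift(zE = 0, zI = 2, u = 0, p)
  expect_equal(d$I, -0.7 * 2)
  ## Wilson-Cowan form: origin fixed point and bounded increments
  pw <- twoStateParams(wEE = matrix(c(0, 0.5, 0.5, 0), 2, 2),
                       C = matrix(c(1, 0), 2, 1))
  expect_equal(twoStateWcDrift(c(0, 0), c(0, 0), 0, pw),
               list(E = c(0, 0), I = c(0, 0)))
  set.seed(11)
  for (rep in 1:10) {
    zE <- rnorm(2, sd = 3); zI <- rnorm(2, sd = 3); u <- rnorm(1, sd = 3)
    d <- twoStateWcDrift(zE, zI, u, pw)
    expect_true(all(abs(d$E + zE) <= 0.5))
    expect_true(all(abs(d$I + zI) <= 0.5))
  }
  expect_error(twoStateParams(matrix(0, 1, 1), wSE = -1, C = matrix(0, 1, 1)),
               "non-negative")
})

test_that("small-signal Wilson-Cowan drift is bilinear with an extra self-decay", {
  ## at alpha = 4, S(x) = x - (4/3) x^3 + O(x^5), so for |x| <= 1e-3 the
  ## W-C drift equals the bilinear drift with A replaced by A - I up to
  ## 2 |x|^3 component-wise
  set.seed(3)
  for (rep in 1:10) {
    l <- 3
    A <- matrix(rnorm(l * l, sd = 0.3), l, l)
    C <- matrix(rnorm(l, sd = 0.3), l, 1)
    pWc <- neuronalParams(A, C = C, alpha = 4)
    pLin <- neuronalParams(A - diag(l), C = C, alpha = 4)
    z <- rnorm(l, sd = 1e-4); u <- rnorm(1, sd = 1e-4)
    x <- drop(A %*% z + C %*% u)
    stopifnot(all(abs(x) <= 1e-3))
    diffs <- abs(wcDrift(z, u, pWc) - bilinearDrift(z, u, pLin))
    expect_true(all(diffs <= 2 * abs(x)^3 + 1e-15))
  }
  ## same argument for the two-state variant
  for (rep in 1:10) {
    t2 <- randomTwoStateInstance(l = 2, m = 1)
    p4 <- twoStateParams(t2$wEE, t2$wSE, t2$wSI, t2$wIE, t2$wEI, t2$C,
                         bEE = t2$bEE, bIE = t2$bIE, alphaE = 4, alphaI = 4)
    zE <- rnorm(2, sd = 1e-4); zI <- rnorm(2, sd = 1e-4)
    u <- rnorm(1, sd = 1e-4)
    dwc <- twoStateWcDrift(zE, zI, u, p4)
    dlin <- twoStateBilinearDrift(zE, zI, u, p4)
    ## bilinear xE uses -wSE zE, W-C uses +wSE zE inside the sigmoid; undo
    ## the sign difference and add the -z relaxation for the comparison
    xE <- dlin$E + 2 * t2$wSE * zE
    xI <- dlin$I
    expect_true(all(abs(dwc$E - (-zE + xE)) <= 2 * abs(xE)^3 + 1e-15))
    expect_true(all(abs(dwc$I - (-zI + xI)) <= 2 * abs(xI)^3 + 1e-15))
  }
})

test_that("ModelSpec invariants are enforced", {
  expect_error(modelSpec(character(0), matrix(TRUE, 0, 0), list(),
                         matrix(TRUE, 0, 1)))
  ## modulation outside the connection mask is rejected
  Am <- diag(2) == 1
  Bm <- matrix(TRUE, 2, 2)
  expect_error(modelSpec(c("a", "b"), Am, Bm, matrix(TRUE, 2, 1)),
               "modulation")
  ## diagonal is forced on
  sp <- modelSpec(c("a", "b"), matrix(FALSE, 2, 2), matrix(FALSE, 2, 2),
                  matrix(TRUE, 2, 1))
  expect_true(all(diag(connectionMask(sp))))
  expect_error(neuronalParams(diag(2), C = matrix(0, 2, 1), alpha = -1),
               "positive")
})
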
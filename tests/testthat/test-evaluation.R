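test_that("the ROC sweep reproduces hand-computed areas", {
  ## perfect separation
  expect_equal(auc(connectionROC(c(0.9, 0.8, 0.2, 0.1),
                                 c(TRUE, TRUE, FALSE, FALSE))), 1)
  ## hand enumeration of concordant pairs: 3 of 4 -> 0.75
  r <- connectionROC(c(0.9, 0.8, 0.4, 0.2), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(auc(r), 0.75)
  expect_equal(r@tpr[1], 0); expect_equal(r@fpr[1], 0)
  expect_equal(tail(r@tpr, 1), 1); expect_equal(tail(r@fpr, 1), 1)
  ## indistinguishable scores: chance
  expect_equal(auc(connectionROC(rep(0.7, 6),
                                 c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))),
               0.5)
  expect_error(connectionROC(c(0.1, 0.9), c(TRUE, TRUE)), "undefined AUC")
})

test_that("the trapezoid AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (rep in 1:5) {
    truth <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    if (!any(truth) || all(truth)) next
    scores <- runif(40)
    ours <- auc(connectionROC(scores, truth))
    ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("recovery metrics reduce to their defining formulas", {
  gt <- groundTruthNetwork("wilson_cowan")
  inp <- standardInputs(duration = 240)
  sim <- integrateDCM(gt$spec, gt$neuronal, inputs = inp, TR = 2)
  post <- invertDCM(sim$bold, inp, gt$spec, opts = list(maxIter = 20))
  rec <- recoveryMetrics(gt$neuronal, post)
  ## identities that hold whatever the fit did
  expect_equal(rec$rmse, sqrt(mean(rec$table$bias^2)))
  expect_equal(rec$correlation,
               cor(rec$table$truth, rec$table$estimate))
  expect_equal(rec$table$bias, rec$table$estimate - rec$table$truth)
  ## perfect recovery degenerates to zero error (synthetic posterior)
  post2 <- post
  post2@mean[rec$table$parameter] <- rec$table$truth
  rec2 <- recoveryMetrics(gt$neuronal, post2)
  expect_equal(rec2$rmse, 0)
  expect_equal(rec2$correlation, 1)
})

test_that("a small SNR sweep is seeded, complete and sane", {
  gt <- groundTruthNetwork()
  inp <- standardInputs(duration = 240)
  sw <- snrSweep(gt$spec, gt$neuronal, inputs = inp, snrGrid = 1,
                 nReal = 2, seed = 5, invertOpts = list(maxIter = 16))
  expect_equal(nrow(sw$summary), 2)   # two variants at one SNR
  expect_true(all(sw$summary$n == 2))
  expect_true(all(is.finite(sw$summary$meanEV)))
  ## identical seed reproduces the table bit-identically
  sw2 <- snrSweep(gt$spec, gt$neuronal, inputs = inp, snrGrid = 1,
                  nReal = 2, seed = 5, invertOpts = list(maxIter = 16))
  expect_identical(sw$summary, sw2$summary)
  ## ROC extraction runs and yields a probability
  roc <- sweepROC(sw, gt$spec, "wilson_cowan")
  expect_true(auc(roc) >= 0 && auc(roc) <= 1)
})

test_that("noise-free data are explained almost perfectly by both variants", {
  gt <- groundTruthNetwork()
  inp <- standardInputs(duration = 240)
  ds <- simulateDataset(gt$spec, gt$neuronal, inputs = inp, snr = Inf,
                        nReal = 1, seed = 1)
  evs <- sapply(c("bilinear", "wilson_cowan"), function(v) {
    spec <- modelSpec(regionNames(gt$spec), connectionMask(gt$spec),
                      modulationMasks(gt$spec), drivingMask(gt$spec),
                      variant = v)
    explainedVarianceOf(invertDCM(ds@noisy[[1]], inp, spec))
  })
  expect_gt(evs["bilinear"], 95)
  ## the benchmark's driving input pushes the linear model's activity to
  ## amplitude ~1, beyond the saturating sigmoid's reach, so the W-C fit of
  ## bilinear-generated data has a structural ceiling just under 95%
  expect_gt(evs["wilson_cowan"], 90)
})
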
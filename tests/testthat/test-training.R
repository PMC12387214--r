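test_that("regularized loss matches closed forms and a scalar-loop oracle", {
  # perfect one-hot predictions, no penalty
  p <- diag(3)[c(1, 2, 3, 1), ] * (1 - 1e-15) + 1e-16
  expect_equal(regularizedLoss(p, c(0L, 1L, 2L, 0L), numeric(0), 0.01), 0,
               tolerance = 1e-12)
  # uniform over 10 classes: ln 10
  u <- matrix(0.1, 5, 10)
  expect_equal(regularizedLoss(u, c(0L, 9L, 3L, 5L, 7L), numeric(0), 0.01),
               log(10), tolerance = 1e-12)
  # seeded random batch vs elementwise summation, penalty included
  set.seed(61)
  z <- matrix(rexp(4 * 3), 4, 3)
  pr <- z / rowSums(z)
  y <- c(2L, 0L, 1L, 2L)
  w <- list(rnorm(5), matrix(rnorm(6), 2, 3))
  lam <- 0.01
  oracle <- 0
  for (i in 1:4) oracle <- oracle - log(pr[i, y[i] + 1]) / 4
  for (wi in w) for (v in wi) oracle <- oracle + lam * v^2
  expect_equal(regularizedLoss(pr, y, w, lam), oracle, tolerance = 1e-10)
  # clamping pathologically small probabilities warns
  bad <- matrix(c(1e-30, 1 - 1e-30), 1, 2)
  expect_warning(l <- regularizedLoss(bad, 0L, numeric(0), 0),
                 "clamped")
  expect_lte(l, -log(1e-12) + 1e-9)
})

test_that("reduce-on-plateau halves after exactly five stagnant epochs and
           floors at the minimum rate", {
  cfg <- trainingConfig()
  # strictly improving: untouched
  expect_equal(nextPlateauLr(seq(1, 0.1, length.out = 12), cfg), 1e-4)
  # five consecutive non-improving epochs trigger one halving
  expect_equal(nextPlateauLr(c(1, rep(1, 4)), cfg), 1e-4)   # only 4 stagnant
  expect_equal(nextPlateauLr(c(1, rep(1, 5)), cfg), 5e-5)
  # counter resets after the reduction: 9 stagnant = still one halving
  expect_equal(nextPlateauLr(c(1, rep(1, 9)), cfg), 5e-5)
  expect_equal(nextPlateauLr(c(1, rep(1, 10)), cfg), 2.5e-5)
  # repeated stagnation clamps at exactly 1e-6, never lower
  expect_equal(nextPlateauLr(c(1, rep(1, 200)), cfg), 1e-6)
})

test_that("early stopping fires after 15 stagnant epochs and restores the
           argmin epoch", {
  cfg <- trainingConfig()
  es <- earlyStop(c(1.0, rep(1.0, 15)), cfg)
  expect_true(es$stop)
  expect_identical(es$restoreEpoch, 1L)
  expect_false(earlyStop(seq(2, 0.2, length.out = 50), cfg)$stop)
  es2 <- earlyStop(c(1.0, 0.9, rep(0.95, 15)), cfg)
  expect_true(es2$stop)
  expect_identical(es2$restoreEpoch, 2L)
})

test_that("short training runs are seed-deterministic and bounded by the
           epoch budget", {
  fx <- syntheticFixture(perClass = 6L, size = 32L, seed = 13L)
  ds <- fx$dataset
  sp <- stratifiedSplit(labels(ds), seed = 5L)
  m <- buildModel(reducedArchitecture(32L), seed = 5L)
  tc <- trainingConfig(learningRate = 1e-3, maxEpochs = 2L, seed = 5L)
  f1 <- trainModel(m, ds, sp, tc)
  f2 <- trainModel(m, ds, sp, tc)
  expect_identical(historyTable(f1$history), historyTable(f2$history))
  expect_lte(nrow(historyTable(f1$history)), 2L)
  expect_s4_class(f1$history, "TrainingHistory")
  h <- historyTable(f1$history)
  expect_true(all(diff(h$lr) <= 0))
  expect_true(all(is.finite(c(h$train_loss, h$val_loss))))
  # the returned model carries the checkpoint with the best validation
  # accuracy seen during the run
  rep <- suppressWarnings(evaluateModel(f1$model, ds, sp$val))
  expect_gte(accuracy(rep) + 1e-9, 0)
})

test_that("a reduced-width model fits an unaugmented synthetic fixture to
           high training accuracy within a few epochs", {
  fx <- syntheticFixture(perClass = 12L, size = 48L, seed = 29L)
  ds <- fx$dataset
  sp <- stratifiedSplit(labels(ds), seed = 3L)
  m <- buildModel(reducedArchitecture(48L), seed = 3L)
  tc <- trainingConfig(learningRate = 3e-3, batchSize = 16L, maxEpochs = 35L,
                       seed = 3L)
  fit <- trainModel(m, ds, sp, tc, augment = NULL)
  trainRep <- evaluateModel(fit$model, ds, sp$train)
  expect_gte(accuracy(trainRep), 0.90)
})
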
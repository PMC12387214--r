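# brute-force per-class metrics by explicit loops (independent oracle)
bruteMetrics <- function(cm) {
  n <- nrow(cm)
  prec <- rec <- f1 <- numeric(n)
  for (c in seq_len(n)) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (prec[c] + rec[c] > 0)
      2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
  }
  list(precision = prec, recall = rec, f1 = f1,
       accuracy = sum(diag(cm)) / sum(cm),
       macro = c(mean(prec), mean(rec), mean(f1)))
}

test_that("confusion matrices tally truth against prediction", {
  y <- c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 0L, 1L)
  p <- c(0L, 1L, 1L, 1L, 2L, 0L, 2L, 0L, 2L)
  cm <- confusionMatrix(y, p, 3L)
  # tallied by hand: true 0 -> predicted (0,1,0); true 1 -> (1,1,2);
  # true 2 -> (2,0,2)
  expect_identical(unname(cm),
                   matrix(c(2L, 1L, 0L,
                            0L, 2L, 1L,
                            1L, 0L, 2L), 3, 3, byrow = TRUE))
  expect_identical(sum(cm), length(y))
  # perfect predictions give a diagonal of supports
  cmp <- confusionMatrix(y, y, 3L)
  expect_identical(unname(diag(cmp)), as.integer(table(y)))
  expect_identical(sum(cmp) - sum(diag(cmp)), 0L)
  expect_error(confusionMatrix(c(0L, 3L), c(0L, 0L), 3L), "out of range")
})

test_that("classification metrics match hand computations", {
  cm <- matrix(c(8L, 2L, 3L, 7L), 2, 2, byrow = TRUE)
  r <- classificationMetrics(cm)
  expect_equal(perClassMetrics(r)$precision[1], 8 / 11, tolerance = 1e-12)
  expect_equal(perClassMetrics(r)$recall[1], 0.8, tolerance = 1e-12)
  expect_equal(perClassMetrics(r)$f1[1], 2 * (8 / 11) * 0.8 / (8 / 11 + 0.8),
               tolerance = 1e-12)
  expect_equal(accuracy(r), 15 / 20, tolerance = 1e-12)
  # perfect matrix: everything 1
  rp <- classificationMetrics(diag(5L) * 9L)
  expect_true(all(perClassMetrics(rp)$f1 == 1))
  expect_identical(accuracy(rp), 1)
})

test_that("metrics agree with the brute-force oracle on random confusion
           matrices", {
  set.seed(71)
  for (trial in 1:100) {
    n <- sample(2:8, 1)
    cm <- matrix(rpois(n * n, lambda = sample(1:20, 1)), n, n)
    if (sum(cm) == 0) cm[1, 1] <- 1
    r <- suppressWarnings(classificationMetrics(cm))
    o <- bruteMetrics(cm)
    expect_equal(perClassMetrics(r)$precision, o$precision, tolerance = 1e-12)
    expect_equal(perClassMetrics(r)$recall, o$recall, tolerance = 1e-12)
    expect_equal(perClassMetrics(r)$f1, o$f1, tolerance = 1e-12)
    expect_equal(accuracy(r), o$accuracy, tolerance = 1e-12)
    expect_equal(unname(macroMetrics(r)), o$macro, tolerance = 1e-12)
  }
})

test_that("zero-denominator conventions and metric invariants hold", {
  # a class never predicted: precision 0 with a warning
  cm <- matrix(c(5L, 0L, 5L, 0L), 2, 2, byrow = TRUE)
  expect_warning(r <- classificationMetrics(cm), "zero-denominator")
  expect_identical(perClassMetrics(r)$precision[2], 0)
  # micro accuracy equals trace/total however labels permute; macro-F1 is
  # permutation invariant
  set.seed(72)
  cm2 <- matrix(rpois(25, 6), 5, 5)
  perm <- sample(5)
  r1 <- suppressWarnings(classificationMetrics(cm2))
  r2 <- suppressWarnings(classificationMetrics(cm2[perm, perm]))
  expect_equal(macroMetrics(r1)["f1"], macroMetrics(r2)["f1"],
               tolerance = 1e-12)
  # harmonic mean lies between precision and recall
  pc <- perClassMetrics(r1)
  expect_true(all(pc$f1 <= pmax(pc$precision, pc$recall) + 1e-12))
  expect_true(all(pc$f1 >= pmin(pc$precision, pc$recall) - 1e-12))
})

test_that("a constant predictor on balanced 10-class data yields the
           degenerate closed-form metrics", {
  y <- rep(0:9, each = 30)
  p <- rep(0L, length(y))
  r <- suppressWarnings(classificationMetrics(confusionMatrix(y, p, 10L)))
  expect_equal(accuracy(r), 0.1, tolerance = 1e-12)
  expect_equal(unname(macroMetrics(r)["f1"]), 2 * 0.1 / 1.1 / 10,
               tolerance = 1e-12)
})

test_that("evaluateModel is consistent with its own confusion matrix", {
  fx <- syntheticFixture(perClass = 6L, size = 32L, seed = 13L)
  ds <- fx$dataset
  sp <- stratifiedSplit(labels(ds), seed = 1L)
  m <- buildModel(reducedArchitecture(32L), seed = 1L)
  r <- suppressWarnings(evaluateModel(m, ds, sp$test))
  r2 <- suppressWarnings(classificationMetrics(confusion(r)))
  expect_equal(perClassMetrics(r), perClassMetrics(r2))
  expect_identical(sum(confusion(r)), length(sp$test))
  expect_error(evaluateModel(m, ds, integer(0)), "empty")
})
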
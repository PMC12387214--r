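# independent oracle: brute-force within-class k nearest neighbors
bruteKnn <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

# does s lie strictly on a segment from some x to one of x's k neighbors?
onSomeSegment <- function(s, xc, nn) {
  for (a in seq_len(nrow(xc))) {
    for (b in nn[a, ]) {
      v <- xc[b, ] - xc[a, ]
      w <- s - xc[a, ]
      t <- sum(w * v) / sum(v * v)
      if (t > 0 && t < 1 && sqrt(sum((w - t * v)^2)) < 1e-9) return(TRUE)
    }
  }
  FALSE
}

test_that("balancing raises every class to the majority count and keeps the
           originals untouched", {
  set.seed(31)
  X <- matrix(runif(15 * 6), 15, 6)
  y <- c(rep(0L, 5), rep(1L, 10))
  out <- smoteBalance(X, y, smoteConfig(kNeighbors = 3L, seed = 2L))
  expect_identical(as.vector(table(out$labels)), c(10L, 10L))
  expect_identical(out$features[1:15, ], X)
  expect_identical(out$labels[1:15], y)
  expect_identical(nrow(out$features), 20L)
})

test_that("every synthetic sample lies on a seed-to-neighbor segment
           (brute-force collinearity oracle)", {
  set.seed(32)
  X <- rbind(matrix(rnorm(40 * 8, mean = 0), 40, 8),
             matrix(rnorm(12 * 8, mean = 3), 12, 8),
             matrix(rnorm(25 * 8, mean = -3), 25, 8))
  y <- rep(0:2, c(40, 12, 25))
  k <- 5L
  out <- smoteBalance(X, y, smoteConfig(kNeighbors = k, seed = 7L))
  expect_identical(as.vector(table(out$labels)), c(40L, 40L, 40L))
  syn <- out$features[-seq_len(nrow(X)), , drop = FALSE]
  synLab <- out$labels[-seq_len(nrow(X))]
  for (i in seq_len(nrow(syn))) {
    xc <- X[y == synLab[i], , drop = FALSE]
    expect_true(onSomeSegment(syn[i, ], xc, bruteKnn(xc, k)))
  }
})

test_that("synthetic features stay inside the per-class envelope", {
  set.seed(33)
  X <- matrix(runif(30 * 5), 30, 5)
  y <- rep(c(0L, 1L), c(10, 20))
  out <- smoteBalance(X, y, smoteConfig(seed = 1L))
  syn <- out$features[-seq_len(30), , drop = FALSE]
  x0 <- X[y == 0L, ]
  expect_true(all(syn >= matrix(apply(x0, 2, min), nrow(syn), 5,
                                byrow = TRUE) - 1e-12))
  expect_true(all(syn <= matrix(apply(x0, 2, max), nrow(syn), 5,
                                byrow = TRUE) + 1e-12))
})

test_that("degenerate classes are clipped or rejected", {
  X <- matrix(runif(8 * 3), 8, 3)
  expect_error(smoteBalance(X, c(0L, rep(1L, 7)), smoteConfig()), "size 1")
  expect_warning(
    out <- smoteBalance(X, c(0L, 0L, 0L, rep(1L, 5)),
                        smoteConfig(kNeighbors = 5L, seed = 3L)),
    "clipped")
  expect_identical(as.vector(table(out$labels)), c(5L, 5L))
})

test_that("plans transfer between feature resolutions (image SMOTE)", {
  set.seed(34)
  imgs <- array(runif(16 * 16 * 3 * 12), c(16, 16, 3, 12))
  y <- rep(c(0L, 1L), c(4, 8))
  bal <- smoteBalanceImages(imgs, y, smoteConfig(kNeighbors = 2L, seed = 5L),
                            searchDownscale = 8L)
  expect_identical(dim(bal$images), c(16L, 16L, 3L, 16L))
  expect_identical(as.vector(table(bal$labels)), c(8L, 8L))
  expect_true(all(bal$images >= 0 & bal$images <= 1))
  # originals preserved bit-exactly
  expect_identical(bal$images[, , , 1:12], imgs)
})

test_that("seeded runs are reproducible", {
  set.seed(35)
  X <- matrix(runif(20 * 4), 20, 4)
  y <- rep(c(0L, 1L), c(6, 14))
  a <- smoteBalance(X, y, smoteConfig(seed = 11L))
  b <- smoteBalance(X, y, smoteConfig(seed = 11L))
  expect_identical(a, b)
})
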
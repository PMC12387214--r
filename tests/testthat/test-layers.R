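# Layer-level numerics checked against independent brute-force oracles.

lf <- fundusnet:::layerForward

# nested-loop dense convolution oracle, zero "same" padding, correlation
bruteConv <- function(x, k, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(k)[1]; kw <- dim(k)[2]; F <- dim(k)[4]
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  y <- array(0, c(H, W, F))
  for (f in seq_len(F)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- b[f]
    for (c in seq_len(C)) for (p in seq_len(kh)) for (q in seq_len(kw)) {
      si <- i + p - 1 - ph; sj <- j + q - 1 - pw
      if (si >= 1 && si <= H && sj >= 1 && sj <= W)
        acc <- acc + k[p, q, c, f] * x[si, sj, c]
    }
    y[i, j, f] <- acc
  }
  y
}

bruteDw <- function(x, k, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(k)[1]; kw <- dim(k)[2]
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  y <- array(0, c(H, W, C))
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- b[c]
    for (p in seq_len(kh)) for (q in seq_len(kw)) {
      si <- i + p - 1 - ph; sj <- j + q - 1 - pw
      if (si >= 1 && si <= H && sj >= 1 && sj <= W)
        acc <- acc + k[p, q, c] * x[si, sj, c]
    }
    y[i, j, c] <- acc
  }
  y
}

# identity batch normalization in inference form: with the epsilon inside the
# square root, the moving variance must be 1 - eps for an exact identity
identityBN <- function(name, c) {
  l <- fundusnet:::mkBN(name, c)
  l$state$movVar <- rep(1 - fundusnet:::BN_EPS, c)
  l
}

dsChain <- function(x, dwK, dwB, pwK, pwB) {
  C <- dim(x)[3]; F <- dim(pwK)[4]
  dw <- fundusnet:::mkDwConv("dw", 3, 3, C); dw$params$k <- dwK; dw$params$b <- dwB
  pw <- fundusnet:::mkConv("pw", 1, 1, C, F); pw$params$k <- pwK; pw$params$b <- pwB
  dim(x) <- c(dim(x), 1L)
  h <- lf(dw, x)$y
  h <- lf(identityBN("b1", C), h)$y
  h <- fundusnet:::reluF(h)
  h <- lf(pw, h)$y
  h <- lf(identityBN("b2", F), h)$y
  h <- fundusnet:::reluF(h)
  array(h, dim(h)[1:3])
}

test_that("depthwise separable convolution matches its composition oracle", {
  set.seed(7)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  # all-zero kernels and biases propagate zero
  z <- dsChain(x, array(0, c(3, 3, 2)), numeric(2),
               array(0, c(1, 1, 2, 3)), numeric(3))
  expect_true(all(z == 0))
  # centre-delta depthwise + identity pointwise reduce to ReLU(X)
  dwK <- array(0, c(3, 3, 2)); dwK[2, 2, ] <- 1
  pwK <- array(0, c(1, 1, 2, 2)); pwK[1, 1, 1, 1] <- 1; pwK[1, 1, 2, 2] <- 1
  expect_equal(dsChain(x, dwK, numeric(2), pwK, numeric(2)),
               fundusnet:::reluF(x), tolerance = 1e-12)
  # seeded random C=2 -> F=3 against the nested-loop oracle
  dwK <- array(rnorm(3 * 3 * 2), c(3, 3, 2)); dwB <- rnorm(2)
  pwK <- array(rnorm(1 * 1 * 2 * 3), c(1, 1, 2, 3)); pwB <- rnorm(3)
  got <- dsChain(x, dwK, dwB, pwK, pwB)
  want <- fundusnet:::reluF(bruteConv(fundusnet:::reluF(bruteDw(x, dwK, dwB)),
                                      pwK, pwB))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("dense convolution matches the brute-force oracle and separable
           kernels compose to an equivalent dense kernel", {
  set.seed(11)
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  k <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4)); b <- rnorm(4)
  xb <- x; dim(xb) <- c(dim(x), 1L)
  got <- fundusnet:::.cpp_conv2d_forward(xb, dim(xb), k, dim(k), b)
  expect_equal(array(got, dim(got)[1:3]), bruteConv(x, k, b),
               tolerance = 1e-10)
  # linear depthwise-then-pointwise equals one dense conv with kernel
  # K[p,q,c,f] = dw[p,q,c] * pw[c,f]
  dwK <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
  pwK <- array(rnorm(3 * 4), c(1, 1, 3, 4))
  keq <- array(0, c(3, 3, 3, 4))
  for (f in 1:4) for (c in 1:3) keq[, , c, f] <- dwK[, , c] * pwK[1, 1, c, f]
  dw <- fundusnet:::.cpp_dwconv_forward(xb, dim(xb), dwK, dim(dwK),
              numeric(3))
  sep <- fundusnet:::.cpp_conv2d_forward(dw, dim(dw), pwK, dim(pwK),
               numeric(4))
  dense <- fundusnet:::.cpp_conv2d_forward(xb, dim(xb), keq, dim(keq),
                 numeric(4))
  expect_equal(sep, dense, tolerance = 1e-6)
})

test_that("squeeze-and-excitation recalibration follows its closed forms", {
  set.seed(3)
  x <- array(rnorm(4 * 4 * 8, sd = 2), c(4, 4, 8, 1))
  se <- fundusnet:::mkSE("se", 8L, 2L)
  # zero weights: sigma(0) = 0.5 gate on every channel
  se0 <- se
  for (p in names(se0$params)) se0$params[[p]][] <- 0
  expect_equal(lf(se0, x)$y, 0.5 * x, tolerance = 1e-12)
  # saturating output bias drives the gate to 1
  seSat <- se0
  seSat$params$b2[] <- 100
  expect_equal(lf(seSat, x)$y, x, tolerance = 1e-12)
  # seeded weights against a scalar-loop evaluation
  y <- lf(se, x)$y
  g <- numeric(8)
  for (c in 1:8) g[c] <- mean(x[, , c, 1])
  z <- pmax(se$params$W1 %*% g + se$params$b1, 0)
  s <- 1 / (1 + exp(-(se$params$W2 %*% z + se$params$b2)))
  want <- x
  for (c in 1:8) want[, , c, 1] <- x[, , c, 1] * s[c]
  expect_equal(y, want, tolerance = 1e-6)
  # the gate lies strictly in (0,1): output never exceeds input in magnitude
  expect_true(all(abs(y) <= abs(x)))
})

test_that("global-context recalibration scales channels into (1, 2)", {
  set.seed(4)
  x <- array(rnorm(3 * 3 * 4), c(3, 3, 4, 1))
  gc <- fundusnet:::mkGC("gc", 4L)
  gc0 <- gc
  for (p in names(gc0$params)) gc0$params[[p]][] <- 0
  expect_equal(lf(gc0, x)$y, 1.5 * x, tolerance = 1e-12)
  # multiplicative gate: zero input stays zero whatever the weights
  expect_true(all(lf(gc, array(0, dim(x)))$y == 0))
  # scalar-loop oracle
  y <- lf(gc, x)$y
  g <- vapply(1:4, function(c) mean(x[, , c, 1]), numeric(1))
  s <- 1 + 1 / (1 + exp(-(gc$params$Wg %*% g + gc$params$bg)))
  want <- x
  for (c in 1:4) want[, , c, 1] <- x[, , c, 1] * s[c]
  expect_equal(y, want, tolerance = 1e-6)
  expect_true(all(abs(y) >= abs(x) & abs(y) <= 2 * abs(x) + 1e-12))
})

test_that("residual block adds an identity-projected skip with no trailing
           activation", {
  set.seed(5)
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4, 1))
  rb <- fundusnet:::mkResBlock("rb", 4L, 4L)
  rb$params$k1[] <- 0; rb$params$k2[] <- 0
  rb$params$ks[] <- 0
  for (c in 1:4) rb$params$ks[1, 1, c, c] <- 1
  for (nm in c("v1", "v2", "vs"))
    rb$state[[nm]] <- rep(1 - fundusnet:::BN_EPS, 4)
  y <- lf(rb, x)$y
  expect_equal(y, x, tolerance = 1e-12)  # would fail if ReLU followed the add
  # shape arithmetic at full width: 9x9x512 in, F = 1024 out
  rb2 <- fundusnet:::mkResBlock("rb2", 512L, 1024L)
  y2 <- lf(rb2, array(0.1, c(9, 9, 512, 1)))$y
  expect_identical(dim(y2), c(9L, 9L, 1024L, 1L))
})

test_that("max pooling drops trailing odd rows with floor semantics", {
  x <- array(seq_len(5 * 5), c(5, 5, 1, 1))
  r <- lf(fundusnet:::mkSimple("p", "maxpool"), x)
  expect_identical(dim(r$y), c(2L, 2L, 1L, 1L))
  expect_equal(r$y[1, 1, 1, 1], max(x[1:2, 1:2, 1, 1]))
  expect_equal(r$y[2, 2, 1, 1], max(x[3:4, 3:4, 1, 1]))
})

test_that("global average pooling is the spatial mean, linear in X", {
  const <- array(3.25, c(4, 5, 2, 1))
  g <- lf(fundusnet:::mkSimple("g", "gap"), const)$y
  expect_equal(as.vector(g), c(3.25, 3.25))
  set.seed(6)
  a <- array(rnorm(4 * 5 * 2 * 3), c(4, 5, 2, 3))
  b <- array(rnorm(4 * 5 * 2 * 3), c(4, 5, 2, 3))
  gsum <- lf(fundusnet:::mkSimple("g", "gap"), 2 * a + b)$y
  expect_equal(gsum,
               2 * lf(fundusnet:::mkSimple("g", "gap"), a)$y +
                 lf(fundusnet:::mkSimple("g", "gap"), b)$y,
               tolerance = 1e-12)
})

test_that("softmax rows normalize for random logits", {
  set.seed(8)
  z <- matrix(rnorm(10 * 32, sd = 5), 10, 32)
  p <- lf(fundusnet:::mkSimple("s", "softmax"), z)$y
  expect_true(all(abs(colSums(p) - 1) <= 1e-6))
  expect_true(all(p > 0 & p < 1))
})

test_that("convolution rejects mismatched channel counts", {
  x <- array(0, c(4, 4, 3, 1))
  k <- array(0, c(3, 3, 2, 4))
  expect_error(fundusnet:::.cpp_conv2d_forward(x, dim(x), k, dim(k),
                     numeric(4)), "channels")
})
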
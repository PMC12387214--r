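test_that("a class score constant in the tapped layer yields an all-zero
           map", {
  m <- buildModel(tinySpec(numClasses = 3L), seed = 6L)
  m@layers$output_dense$params$W[] <- 0  # logits independent of features
  set.seed(81)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  sal <- gradCAM(m, img, 1L)
  expect_identical(max(saliencyValues(sal)), 0)
  salpp <- gradCAMpp(m, img, 1L)
  expect_identical(max(saliencyValues(salpp)), 0)
})

test_that("single-channel toy with score = sum of activations reduces to the
           normalized rectified activation map", {
  m <- sumScoreToyModel(inputSize = 6L, seed = 2L)
  set.seed(82)
  img <- array(runif(6 * 6 * 1), c(6, 6, 1))
  fw <- modelForward(m, array(img, c(6, 6, 1, 1)), keepCache = TRUE)
  A <- fw$acts$tap_conv[, , 1, 1]
  sal <- gradCAM(m, img, 1L, layer = "tap_conv")
  rel <- pmax(A, 0)
  want <- if (max(rel) > min(rel)) (rel - min(rel)) / (max(rel) - min(rel))
          else rel * 0
  # tap is already at input resolution: upsampling is the identity here
  expect_equal(saliencyValues(sal), want, tolerance = 1e-9)
  # with position-uniform gradients, Grad-CAM++ agrees after normalization
  salpp <- gradCAMpp(m, img, 1L, layer = "tap_conv")
  expect_equal(saliencyValues(salpp), saliencyValues(sal), tolerance = 1e-9)
})

test_that("internal CAM gradients agree with central finite differences", {
  m <- buildModel(tinySpec(numClasses = 3L), seed = 9L)
  set.seed(83)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  layer <- "block2_pool"
  cg <- fundusnet:::camGradients(m, img, 2L, layer)
  fw <- modelForward(m, img, keepCache = TRUE)
  A <- fw$acts[[layer]]
  fd <- function(ii, h) {
    Ap <- A; Ap[ii] <- Ap[ii] + h
    Am <- A; Am[ii] <- Am[ii] - h
    (modelForward(m, Ap, fromLayer = layer)$logits[1, 3] -
       modelForward(m, Am, fromLayer = layer)$logits[1, 3]) / (2 * h)
  }
  worst <- 0
  checked <- 0
  # only probe positions with clearly nonzero activation: at A == 0 the
  # rectified network sits exactly on a kink and the gradient is undefined
  live <- which(abs(A) > 1e-3)
  for (ii in sample(live, min(20, length(live)))) {
    num <- fd(ii, 1e-5)
    # skip positions within the step of a ReLU/max-pool kink, where central
    # differences straddle the non-smoothness (halving h changes the slope)
    if (abs(num - fd(ii, 5e-6)) > 1e-6 * max(1, abs(num))) next
    an <- cg$grad[ii]
    if (abs(num) > 1e-8 || abs(an) > 1e-8) {
      worst <- max(worst, abs(num - an) / max(abs(num), abs(an)))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 5)
  expect_lt(worst, 1e-3)
})

test_that("scaling all logits by a positive constant leaves the normalized
           Grad-CAM map unchanged", {
  m <- buildModel(tinySpec(numClasses = 3L), seed = 12L)
  set.seed(84)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  s1 <- gradCAM(m, img, 0L)
  m2 <- m
  m2@layers$output_dense$params$W <- 3.7 * m2@layers$output_dense$params$W
  m2@layers$output_dense$params$b <- 3.7 * m2@layers$output_dense$params$b
  s2 <- gradCAM(m2, img, 0L)
  expect_equal(saliencyValues(s1), saliencyValues(s2), tolerance = 1e-9)
})

test_that("Grad-CAM++ position weights are guarded: no NaN over random toy
           models", {
  for (trial in 1:25) {
    m <- buildModel(tinySpec(numClasses = 3L), seed = 100L + trial)
    set.seed(trial)
    img <- array(runif(32 * 32 * 3), c(32, 32, 3))
    v <- saliencyValues(gradCAMpp(m, img, sample(0:2, 1)))
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("non-spatial layers and bad class indices are rejected", {
  m <- buildModel(tinySpec(numClasses = 3L), seed = 1L)
  img <- array(0.5, c(32, 32, 3))
  expect_error(gradCAM(m, img, 0L, layer = "fc1"), "not a spatial")
  expect_error(gradCAM(m, img, 7L), "classIndex")
})

test_that("overlays are convex blends clipped to range", {
  set.seed(85)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  map <- matrix(runif(32 * 32), 32, 32)
  expect_equal(overlayHeatmap(img, map, alpha = 0), img, tolerance = 1e-12)
  heat <- overlayHeatmap(img, map, alpha = 1)
  expect_equal(heat, overlayHeatmap(img * 0, map, alpha = 1),
               tolerance = 1e-12)  # alpha = 1 ignores the image
  mid <- overlayHeatmap(img, map, alpha = 0.4)
  expect_true(all(mid >= 0 & mid <= 1))
  expect_error(overlayHeatmap(img, matrix(0, 8, 8)), "resolutions differ")
})
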
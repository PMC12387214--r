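#' @include AllClasses.R model.R
NULL

# forward to logits with caches, then gradient of the target class logit
# w.r.t. the tapped layer's activations (inference-mode backprop)
camGradients <- function(model, image, classIndex, layer) {
  if (length(dim(image)) == 3L) dim(image) <- c(dim(image), 1L)
  fw <- modelForward(model, image, training = FALSE, keepCache = TRUE)
  A <- fw$acts[[layer]]
  if (is.null(A) || length(dim(A)) != 4L)
    stop("layer '", layer, "' is not a spatial tap point")
  n <- model@spec@numClasses
  if (classIndex < 0L || classIndex >= n)
    stop("classIndex must lie in [0, ", n, ")")
  dL <- matrix(0, n, 1)
  dL[classIndex + 1L, 1] <- 1
  bw <- modelBackward(model, fw$caches, dL, training = FALSE,
                      stopLayer = layer)
  list(A = array(A, dim(A)[1:3]),          # keep 3-d even for one channel
       grad = array(bw$dOut, dim(A)[1:3]),
       logits = fw$logits[1, ], probs = fw$probs[1, ])
}

# ReLU, upsample to input resolution, min-max normalize (all-zero maps stay
# all-zero: no division when max == min)
finalizeMap <- function(raw, model, layer, classIndex, method) {
  raw[raw < 0] <- 0
  up <- .cpp_bilinear_resize(raw, model@spec@inputHeight,
                             model@spec@inputWidth)
  rng <- range(up)
  vals <- if (rng[2] > rng[1]) (up - rng[1]) / (rng[2] - rng[1])
          else matrix(0, nrow(up), ncol(up))
  new("SaliencyMap", values = vals, sourceLayer = layer,
      classIndex = as.integer(classIndex), method = method)
}

#' Grad-CAM saliency map
#'
#' Class-conditional saliency from a convolutional tap point: the gradient of
#' the pre-softmax class score with respect to the tapped activations is
#' averaged over space to give one weight per channel; the weighted channel
#' sum is rectified, bilinearly upsampled to input resolution and min-max
#' normalized to [0, 1]. A class score that is constant with respect to the
#' tapped layer yields an all-zero map.
#'
#' @param model A \linkS4class{FundusModel}.
#' @param image (H, W, C) image in [0, 1].
#' @param classIndex 0-based target class.
#' @param layer Tap layer name; default \code{"block4_res"}, the residual
#'   block output before the final pool (highest-resolution deep features).
#' @return A \linkS4class{SaliencyMap}.
#' @export
gradCAM <- function(model, image, classIndex, layer = "block4_res") {
  cg <- camGradients(model, image, classIndex, layer)
  alpha <- apply(cg$grad, 3, mean)              # spatial mean per channel
  raw <- matrix(0, dim(cg$A)[1], dim(cg$A)[2])
  for (k in seq_along(alpha)) raw <- raw + alpha[k] * cg$A[, , k]
  finalizeMap(raw, model, layer, classIndex, "gradcam")
}

#' Grad-CAM++ saliency map
#'
#' Refinement of Grad-CAM with position-wise weights built from second- and
#' third-order derivatives of exp(class score). With g the gradient of the
#' class logit w.r.t. the activations, the derivatives of exp(y) reduce to
#' exp(y) g^k, so the position weights are
#' alpha = g^2 / (2 g^2 + sum_ab(A_ab) g^3 + eps) and the channel weights
#' w_k = sum_ij alpha_ij ReLU(g_ij). The weighted channel sum is rectified,
#' upsampled and normalized exactly as in \code{\link{gradCAM}}.
#'
#' @inheritParams gradCAM
#' @return A \linkS4class{SaliencyMap}.
#' @export
gradCAMpp <- function(model, image, classIndex, layer = "block4_res") {
  cg <- camGradients(model, image, classIndex, layer)
  d <- dim(cg$A)
  raw <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) {
    g <- cg$grad[, , k]
    g2 <- g * g
    g3 <- g2 * g
    denom <- 2 * g2 + sum(cg$A[, , k]) * g3
    alpha <- ifelse(abs(denom) > 1e-8, g2 / (denom + 1e-8 * sign(denom)), 0)
    wk <- sum(alpha * pmax(g, 0))
    raw <- raw + wk * cg$A[, , k]
  }
  finalizeMap(raw, model, layer, classIndex, "gradcampp")
}

# piecewise-linear jet colormap on [0, 1] -> (n, 3) RGB
jetColors <- function(v) {
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  cbind(r, g, b)
}

#' Overlay a saliency map on an image
#'
#' Convex blend of the image with the color-mapped heatmap:
#' \code{(1 - alpha) * image + alpha * colormap(map)}, clipped to [0, 1].
#'
#' @param image (H, W, 3) image in [0, 1].
#' @param map A \linkS4class{SaliencyMap} (or H x W matrix in [0, 1]) at the
#'   same resolution.
#' @param alpha Blend weight in [0, 1] (default 0.4).
#' @return (H, W, 3) array in [0, 1].
#' @export
overlayHeatmap <- function(image, map, alpha = 0.4) {
  vals <- if (is(map, "SaliencyMap")) map@values else map
  d <- dim(image)
  if (d[1] != nrow(vals) || d[2] != ncol(vals))
    stop("image (", d[1], "x", d[2], ") and saliency map (", nrow(vals), "x",
         ncol(vals), ") resolutions differ")
  stopifnot(alpha >= 0, alpha <= 1)
  heat <- array(jetColors(as.vector(vals)), c(d[1], d[2], 3L))
  out <- (1 - alpha) * image + alpha * heat
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}
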
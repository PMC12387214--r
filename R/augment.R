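#' Augmentation configuration
#'
#' Ranges of the random geometric transforms applied to training batches:
#' rotation up to 20 degrees, width/height shift up to 10\%, shear, zoom and
#' horizontal flip. All draws are per image and independent; out-of-bounds
#' pixels are filled with the nearest border pixel and interpolation is
#' bilinear.
#'
#' @param rotationDeg Max absolute rotation in degrees (default 20).
#' @param shiftFrac Max absolute width/height shift as a fraction of the
#'   image size (default 0.10).
#' @param shearFrac Max absolute shear factor (default 0.10).
#' @param zoomFrac Max absolute zoom deviation from 1 (default 0.10).
#' @param horizontalFlip Flip left-right with probability 0.5 (default TRUE).
#' @return A validated list of class \code{"AugmentationConfig"}.
#' @export
augmentationConfig <- function(rotationDeg = 20, shiftFrac = 0.10,
                               shearFrac = 0.10, zoomFrac = 0.10,
                               horizontalFlip = TRUE) {
  stopifnot(rotationDeg >= 0, shiftFrac >= 0, shearFrac >= 0, zoomFrac >= 0)
  structure(list(rotationDeg = rotationDeg, shiftFrac = shiftFrac,
                 shearFrac = shearFrac, zoomFrac = zoomFrac,
                 horizontalFlip = isTRUE(horizontalFlip)),
            class = "AugmentationConfig")
}

#' Randomly augment an image batch
#'
#' Applies, per image, an independent random rotation, shift, shear and zoom
#' (composed into a single inverse-mapped affine warp with bilinear sampling
#' and clamp-to-edge fill) and an optional horizontal flip with probability
#' 0.5. Draws come from the session RNG, so results are reproducible under
#' \code{set.seed}. Output values are clipped to [0, 1]; shapes are
#' unchanged. Intended for the training stream only, resampled every epoch.
#'
#' @param imgs (H, W, C, B) array in [0, 1].
#' @param config An \code{\link{augmentationConfig}}.
#' @return Augmented array of the same shape.
#' @export
augmentBatch <- function(imgs, config = augmentationConfig()) {
  d <- dim(imgs)
  out <- imgs
  identityCfg <- config$rotationDeg == 0 && config$shiftFrac == 0 &&
    config$shearFrac == 0 && config$zoomFrac == 0
  for (b in seq_len(d[4])) {
    theta <- stats::runif(1, -config$rotationDeg, config$rotationDeg) * pi / 180
    dyx <- stats::runif(2, -config$shiftFrac, config$shiftFrac) * d[1:2]
    sh <- stats::runif(1, -config$shearFrac, config$shearFrac)
    zm <- 1 + stats::runif(1, -config$zoomFrac, config$zoomFrac)
    doFlip <- config$horizontalFlip && stats::runif(1) < 0.5
    img <- imgs[, , , b]
    if (doFlip) img <- img[, d[2]:1, , drop = FALSE]
    if (!identityCfg) {
      # forward map M = R(theta) %*% Shear %*% Zoom on (row, col) offsets;
      # the sampler needs the inverse: src = M^-1 (p - c) + c - M^-1 t
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      S <- matrix(c(1, 0, sh, 1), 2, 2)
      M <- R %*% S %*% diag(c(zm, zm))
      A <- solve(M)
      tt <- -as.vector(A %*% dyx)
      img <- .cpp_warp_affine(img, dim(img), as.vector(A), tt)
    }
    out[, , , b] <- img
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}
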
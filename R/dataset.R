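#' @include AllClasses.R
NULL

# read one image file to an (H, W, 3) array in [0, 1]; bilinear resize
readImageFile <- function(path, targetSize) {
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) == EBImage::Grayscale)
    img <- EBImage::toRGB(img)
  img <- EBImage::resize(img, w = targetSize, h = targetSize,
                         filter = "bilinear")
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  a <- aperm(a, c(2, 1, 3))  # EBImage stores (x, y, c); we use (row, col, c)
  a[a < 0] <- 0; a[a > 1] <- 1
  a
}

#' Load a class-foldered image dataset
#'
#' Reads a directory tree with one subdirectory per class (JPEG/PNG), resizes
#' every image bilinearly to \code{targetSize} x \code{targetSize}, converts
#' to RGB and scales 8-bit intensities to [0, 1] (255 maps to exactly 1).
#' Class indices are 0-based positions in the sorted class-directory list,
#' recorded with each file in the manifest. Files that cannot be decoded are
#' skipped with a warning; an empty class directory is an error.
#'
#' @param rootDir Directory containing one subdirectory per class.
#' @param targetSize Output size in pixels (default 150).
#' @return A \linkS4class{FundusDataset}.
#' @export
loadDataset <- function(rootDir, targetSize = 150L) {
  if (!dir.exists(rootDir)) stop("no such directory: ", rootDir)
  classes <- sort(list.dirs(rootDir, recursive = FALSE, full.names = FALSE))
  if (!length(classes)) stop("no class subdirectories under ", rootDir)
  paths <- list(); labs <- integer(0)
  for (ci in seq_along(classes)) {
    fs <- sort(list.files(file.path(rootDir, classes[ci]),
                          pattern = "\\.(png|jpg|jpeg|PNG|JPG|JPEG)$",
                          full.names = TRUE))
    if (!length(fs))
      stop("class directory '", classes[ci], "' contains no decodable images")
    paths[[ci]] <- fs
    labs <- c(labs, rep(ci - 1L, length(fs)))
  }
  paths <- unlist(paths)
  imgs <- array(0, c(targetSize, targetSize, 3L, length(paths)))
  keep <- logical(length(paths))
  for (i in seq_along(paths)) {
    a <- tryCatch(readImageFile(paths[i], targetSize), error = function(e) {
      warning("skipping undecodable file ", paths[i], ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(a)) { imgs[, , , i] <- a; keep[i] <- TRUE }
  }
  imgs <- imgs[, , , keep, drop = FALSE]
  labs <- labs[keep]
  man <- data.frame(path = paths[keep],
                    class_name = classes[labs + 1L],
                    class_index = labs, stringsAsFactors = FALSE)
  new("FundusDataset", images = imgs, labels = labs, classNames = classes,
      manifest = man)
}

#' Flatten an image stack to a feature matrix
#'
#' Row-per-image flattening used before feature-space SMOTE. Optionally
#' downsamples each image bilinearly first, since nearest-neighbor search at
#' full 150x150x3 resolution is memory-heavy.
#'
#' @param imgs (H, W, C, n) image array.
#' @param downscale Optional smaller spatial size to resize to before
#'   flattening (NULL keeps full resolution).
#' @return n x d numeric matrix.
#' @export
flattenImages <- function(imgs, downscale = NULL) {
  d <- dim(imgs)
  n <- d[4]
  if (!is.null(downscale) && downscale < d[1]) {
    out <- matrix(0, n, downscale * downscale * d[3])
    for (i in seq_len(n)) {
      ch <- lapply(seq_len(d[3]), function(c)
        .cpp_bilinear_resize(imgs[, , c, i], downscale, downscale))
      out[i, ] <- unlist(ch)
    }
    out
  } else {
    t(matrix(imgs, prod(d[1:3]), n))
  }
}

#' Restore flattened features to an image stack
#'
#' Inverse of \code{\link{flattenImages}} at full resolution, clipping to
#' [0, 1] (SMOTE interpolates inside the data envelope, so clipping is a
#' no-op for in-range inputs).
#'
#' @param feats n x (H*W*C) matrix.
#' @param height,width,channels Target image geometry.
#' @return (H, W, C, n) array.
#' @export
unflattenImages <- function(feats, height, width, channels = 3L) {
  x <- array(t(feats), c(height, width, channels, nrow(feats)))
  x[x < 0] <- 0; x[x > 1] <- 1
  x
}
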
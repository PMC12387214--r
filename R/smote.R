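#' SMOTE configuration
#'
#' @param kNeighbors Number of same-class nearest neighbors considered when
#'   interpolating (classical default 5). Clipped per class to class size - 1
#'   with a warning when a class is too small.
#' @param targetCount Either \code{"majority"} (balance every class up to the
#'   largest class) or an explicit per-class count.
#' @param seed Integer RNG seed.
#' @return A validated list of class \code{"SmoteConfig"}.
#' @export
smoteConfig <- function(kNeighbors = 5L, targetCount = "majority", seed = 1L) {
  stopifnot(kNeighbors >= 1L)
  if (!identical(targetCount, "majority"))
    stopifnot(is.numeric(targetCount), targetCount >= 1)
  structure(list(kNeighbors = as.integer(kNeighbors),
                 targetCount = targetCount, seed = as.integer(seed)),
            class = "SmoteConfig")
}

#' Balance classes with feature-space SMOTE
#'
#' Synthetic minority oversampling: every class is brought up to the target
#' count (the majority class size by default) by interpolating new samples
#' between existing minority samples and their k nearest same-class
#' neighbors (Euclidean metric). Each synthetic sample is
#' \code{s = x + u * (xn - x)} with a single \code{u ~ U(0, 1)} applied to
#' all features, \code{x} a class sample and \code{xn} one of its k nearest
#' neighbors within the class. Original rows are preserved unchanged and come
#' first in the output, in their input order.
#'
#' @param features n x d numeric matrix (e.g. flattened images).
#' @param classLabels Integer vector of length n.
#' @param config A \code{\link{smoteConfig}}.
#' @return List with \code{features} (m x d) and \code{labels} (length m);
#'   m = numberOfClasses x targetCount when balancing to the majority.
#' @export
smoteBalance <- function(features, classLabels, config = smoteConfig()) {
  plan <- smotePlan(features, classLabels, config)
  applySmotePlan(features, classLabels, plan)
}

#' Plan SMOTE interpolations
#'
#' Computes, without synthesizing anything, which (seed sample, same-class
#' nearest neighbor, interpolation weight u) triples SMOTE will use. The plan
#' can then be applied to the same feature matrix
#' (\code{\link{applySmotePlan}}) or to a parallel matrix of the same rows at
#' a different feature resolution, which lets the neighbor search run in a
#' reduced space while synthesis stays at full resolution.
#'
#' @inheritParams smoteBalance
#' @return data.frame with columns label, seed_row, neighbor_row (global row
#'   indices into \code{features}) and u.
#' @export
smotePlan <- function(features, classLabels, config = smoteConfig()) {
  stopifnot(is.matrix(features), nrow(features) == length(classLabels))
  classLabels <- as.integer(classLabels)
  counts <- table(classLabels)
  if (any(counts < 2L))
    stop("SMOTE cannot interpolate classes of size 1 (classes: ",
         paste(names(counts)[counts < 2L], collapse = ", "), ")")
  target <- if (identical(config$targetCount, "majority")) max(counts)
            else as.integer(config$targetCount)
  set.seed(config$seed)
  plans <- list()
  for (cl in as.integer(names(counts))) {
    idx <- which(classLabels == cl)
    need <- target - length(idx)
    if (need <= 0L) next
    k <- config$kNeighbors
    if (k > length(idx) - 1L) {
      k <- length(idx) - 1L
      warning("class ", cl, ": k clipped to ", k,
              " (class has only ", length(idx), " samples)", call. = FALSE)
    }
    xc <- features[idx, , drop = FALSE]
    # pairwise squared Euclidean distances within the class
    sq <- rowSums(xc^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(xc)
    diag(d2) <- Inf
    nnIdx <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
    seedRows <- rep_len(seq_along(idx), need)
    pickNb <- sample.int(k, need, replace = TRUE)
    plans[[length(plans) + 1L]] <- data.frame(
      label = cl, seed_row = idx[seedRows],
      neighbor_row = idx[nnIdx[cbind(seedRows, pickNb)]],
      u = stats::runif(need))
  }
  if (length(plans)) do.call(rbind, plans)
  else data.frame(label = integer(0), seed_row = integer(0),
                  neighbor_row = integer(0), u = numeric(0))
}

#' Apply a SMOTE plan
#'
#' Synthesizes \code{s = x + u * (xn - x)} for every plan row and appends the
#' results (originals first, unchanged).
#'
#' @inheritParams smoteBalance
#' @param plan A \code{\link{smotePlan}} result.
#' @return List with \code{features} and \code{labels}.
#' @export
applySmotePlan <- function(features, classLabels, plan) {
  if (!nrow(plan))
    return(list(features = features, labels = as.integer(classLabels)))
  a <- features[plan$seed_row, , drop = FALSE]
  b <- features[plan$neighbor_row, , drop = FALSE]
  syn <- a + plan$u * (b - a)
  list(features = rbind(features, syn),
       labels = c(as.integer(classLabels), plan$label))
}

#' SMOTE-balance an image stack
#'
#' Feature-space SMOTE on flattened images, returning a balanced image stack.
#' When \code{searchDownscale} is given, nearest neighbors are found on
#' bilinearly downscaled copies (much lighter distance computations) while
#' the interpolation itself runs on the full-resolution pixels, so outputs
#' are always full-size images in [0, 1].
#'
#' @param imgs (H, W, C, n) array in [0, 1].
#' @param classLabels Integer labels of length n.
#' @param config A \code{\link{smoteConfig}}.
#' @param searchDownscale Optional spatial size for the neighbor search.
#' @return List with \code{images} ((H, W, C, m) array) and \code{labels}.
#' @export
smoteBalanceImages <- function(imgs, classLabels, config = smoteConfig(),
                               searchDownscale = NULL) {
  full <- flattenImages(imgs)
  search <- if (is.null(searchDownscale)) full
            else flattenImages(imgs, downscale = searchDownscale)
  plan <- smotePlan(search, classLabels, config)
  out <- applySmotePlan(full, classLabels, plan)
  d <- dim(imgs)
  list(images = unflattenImages(out$features, d[1], d[2], d[3]),
       labels = out$labels)
}
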
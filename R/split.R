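#' Stratified train/validation/test split
#'
#' Partitions sample indices into train/validation/test sets preserving
#' per-class proportions. Split totals are fixed first by largest-remainder
#' rounding of the global fractions (ties resolved toward the later split,
#' so the test set receives the half-sample on an exact .5 tie); per-class
#' cell counts then start from floored quotas and the remaining samples are
#' assigned greedily by largest fractional remainder, subject to the fixed
#' split totals, with seeded random tie-breaking. Every class therefore lands
#' within one sample of its exact quota in every split.
#'
#' @param classLabels Integer vector of class labels.
#' @param fractions Numeric length-3 vector summing to 1
#'   (default c(0.70, 0.15, 0.15)).
#' @param seed Integer seed (tie-breaking and within-class shuffling).
#' @return List of class \code{"SplitBundle"}: integer index vectors
#'   \code{train}, \code{val}, \code{test} (1-based, disjoint, exhaustive),
#'   plus \code{fractions} and \code{seed}.
#' @export
stratifiedSplit <- function(classLabels, fractions = c(0.70, 0.15, 0.15),
                            seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3L)
  classLabels <- as.integer(classLabels)
  counts <- table(classLabels)
  if (any(counts < 3L))
    stop("every class needs at least 3 samples to appear in all three ",
         "splits (too small: ",
         paste(names(counts)[counts < 3L], collapse = ", "), ")")
  set.seed(seed)
  n <- length(classLabels)
  # global split totals by largest remainder, ties toward the later split
  q <- fractions * n
  tot <- floor(q)
  rem <- n - sum(tot)
  if (rem > 0) {
    ord <- order(q - tot, seq_along(q), decreasing = TRUE)  # later split wins ties
    tot[ord[seq_len(rem)]] <- tot[ord[seq_len(rem)]] + 1
  }
  classes <- as.integer(names(counts))
  nc <- length(classes)
  base <- matrix(0, nc, 3)
  fr <- matrix(0, nc, 3)
  for (i in seq_len(nc)) {
    qc <- fractions * counts[i]
    base[i, ] <- floor(qc)
    fr[i, ] <- qc - base[i, ]
  }
  deficitClass <- counts - rowSums(base)
  deficitSplit <- tot - colSums(base)
  # greedy largest-remainder assignment under the split-total constraints,
  # at most one extra per (class, split) cell so no class drifts more than
  # one sample from its quota in any split
  extra <- matrix(0L, nc, 3)
  cells <- expand.grid(ci = seq_len(nc), si = 1:3)
  cells$fr <- fr[cbind(cells$ci, cells$si)]
  cells <- cells[order(-cells$fr, stats::runif(nrow(cells))), ]
  give <- function(ci, si) {
    extra[ci, si] <<- 1L
    deficitClass[ci] <<- deficitClass[ci] - 1
    deficitSplit[si] <<- deficitSplit[si] - 1
  }
  for (r in seq_len(nrow(cells))) {
    ci <- cells$ci[r]; si <- cells$si[r]
    if (deficitClass[ci] > 0 && deficitSplit[si] > 0 && extra[ci, si] == 0L)
      give(ci, si)
  }
  # repair pass: a starved class donates from an over-subscribed split by
  # moving another class's extra to a split that still has room
  guard <- 0L
  while (any(deficitClass > 0) && guard < 10L * nc) {
    guard <- guard + 1L
    ci <- which(deficitClass > 0)[1]
    placed <- FALSE
    for (si in order(-fr[ci, ])) {
      if (extra[ci, si] == 1L) next
      if (deficitSplit[si] > 0) { give(ci, si); placed <- TRUE; break }
      donors <- which(extra[, si] == 1L & seq_len(nc) != ci)
      for (dn in donors) {
        s2 <- which(deficitSplit > 0 & extra[dn, ] == 0L)
        if (length(s2)) {
          extra[dn, si] <- 0L; extra[dn, s2[1]] <- 1L
          deficitSplit[si] <- deficitSplit[si] + 1
          deficitSplit[s2[1]] <- deficitSplit[s2[1]] - 1
          give(ci, si)
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) break
  }
  stopifnot(all(deficitClass == 0), all(deficitSplit == 0))
  base <- base + extra
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (i in seq_len(nc)) {
    idx <- sample(which(classLabels == classes[i]))
    out$train <- c(out$train, idx[seq_len(base[i, 1])])
    out$val <- c(out$val, idx[base[i, 1] + seq_len(base[i, 2])])
    out$test <- c(out$test, idx[base[i, 1] + base[i, 2] + seq_len(base[i, 3])])
  }
  structure(list(train = sort(out$train), val = sort(out$val),
                 test = sort(out$test), fractions = fractions,
                 seed = as.integer(seed)),
            class = "SplitBundle")
}
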
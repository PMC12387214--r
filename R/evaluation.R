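#' @include AllClasses.R model.R training.R
NULL

#' Confusion matrix from label vectors
#'
#' Counts, for every (true, predicted) class pair, the number of samples:
#' rows are true classes, columns predicted classes.
#'
#' @param trueLabels,predictedLabels Integer vectors of 0-based labels.
#' @param numClasses Number of classes N.
#' @param classLabels Optional class names for dimnames.
#' @return N x N integer matrix.
#' @export
confusionMatrix <- function(trueLabels, predictedLabels, numClasses,
                            classLabels = NULL) {
  trueLabels <- as.integer(trueLabels)
  predictedLabels <- as.integer(predictedLabels)
  stopifnot(length(trueLabels) == length(predictedLabels))
  if (any(c(trueLabels, predictedLabels) < 0L) ||
      any(c(trueLabels, predictedLabels) >= numClasses))
    stop("labels out of range [0, ", numClasses, ")")
  cm <- matrix(0L, numClasses, numClasses)
  for (i in seq_along(trueLabels))
    cm[trueLabels[i] + 1L, predictedLabels[i] + 1L] <-
      cm[trueLabels[i] + 1L, predictedLabels[i] + 1L] + 1L
  if (is.null(classLabels)) classLabels <- as.character(seq_len(numClasses) - 1L)
  dimnames(cm) <- list(true = classLabels, predicted = classLabels)
  cm
}

#' Per-class and macro classification metrics
#'
#' One-vs-rest precision, recall and F1 per class from a confusion matrix
#' (TP the diagonal entry, FP the remaining column, FN the remaining row),
#' their unweighted macro averages, and overall accuracy (trace over total).
#' Metrics with a zero denominator (e.g. a class never predicted) are
#' reported as 0 with a warning.
#'
#' @param cm N x N confusion matrix (rows = true, columns = predicted).
#' @return A \linkS4class{MetricsReport}.
#' @export
classificationMetrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), sum(cm) > 0)
  n <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  degenerate <- (tp + fp == 0) | (tp + fn == 0)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  if (any(degenerate))
    warning("zero-denominator metrics reported as 0 for class(es): ",
            paste(rownames(cm)[degenerate], collapse = ", "), call. = FALSE)
  cls <- if (!is.null(rownames(cm))) rownames(cm)
         else as.character(seq_len(n) - 1L)
  per <- data.frame(class = cls, precision = precision, recall = recall,
                    f1 = f1, support = rowSums(cm), row.names = NULL)
  new("MetricsReport", confusionMatrix = cm, perClass = per,
      macro = c(precision = mean(precision), recall = mean(recall),
                f1 = mean(f1)),
      overallAccuracy = sum(tp) / sum(cm))
}

#' Evaluate a model on held-out indices
#'
#' Runs inference on the given samples, takes the argmax class per image and
#' reports the confusion matrix with per-class and macro metrics.
#'
#' @param model A trained \linkS4class{FundusModel}.
#' @param dataset A \linkS4class{FundusDataset}.
#' @param indices Integer sample indices (e.g. \code{split$test}).
#' @return A \linkS4class{MetricsReport}.
#' @export
evaluateModel <- function(model, dataset, indices) {
  if (!length(indices)) stop("empty evaluation split")
  probs <- predictInBatches(model, dataset@images, indices)
  pred <- max.col(probs, ties.method = "first") - 1L
  cm <- confusionMatrix(dataset@labels[indices], pred,
                        model@spec@numClasses, dataset@classNames)
  classificationMetrics(cm)
}

#' Write a metrics report to disk
#'
#' Persists the confusion matrix as CSV, the full report as JSON and a
#' plain-text per-class table (precision/recall/F1 and support, 3 decimals).
#'
#' @param report A \linkS4class{MetricsReport}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeMetricsReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cmPath <- file.path(dir, "confusion_matrix.csv")
  utils::write.csv(as.data.frame(confusion(report)), cmPath)
  js <- list(accuracy = report@overallAccuracy,
             macro = as.list(report@macro),
             per_class = report@perClass)
  jsPath <- file.path(dir, "metrics.json")
  jsonlite::write_json(js, jsPath, auto_unbox = TRUE, digits = NA)
  txt <- report@perClass
  txt$precision <- sprintf("%.3f", txt$precision)
  txt$recall <- sprintf("%.3f", txt$recall)
  txt$f1 <- sprintf("%.3f", txt$f1)
  txtPath <- file.path(dir, "metrics.txt")
  writeLines(c(sprintf("%-38s %9s %9s %9s %9s", "class", "precision",
                       "recall", "f1", "support"),
               sprintf("%-38s %9s %9s %9s %9d", txt$class, txt$precision,
                       txt$recall, txt$f1, txt$support),
               sprintf("%-38s %9.3f %9.3f %9.3f %9d", "macro avg",
                       report@macro["precision"], report@macro["recall"],
                       report@macro["f1"], sum(report@perClass$support)),
               sprintf("accuracy %.3f", report@overallAccuracy)), txtPath)
  invisible(c(cmPath, jsPath, txtPath))
}
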
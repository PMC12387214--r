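#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @aliases images,FundusDataset-method
setMethod("images", "FundusDataset", function(x) x@images)

#' @rdname accessors
#' @aliases labels,FundusDataset-method
setMethod("labels", "FundusDataset", function(object, ...) object@labels)

#' @rdname accessors
#' @aliases classNames,FundusDataset-method
setMethod("classNames", "FundusDataset", function(x) x@classNames)

#' @rdname accessors
#' @aliases manifest,FundusDataset-method
setMethod("manifest", "FundusDataset", function(x) x@manifest)

#' @rdname accessors
#' @aliases historyTable,TrainingHistory-method
setMethod("historyTable", "TrainingHistory", function(x) x@records)

#' @rdname accessors
#' @aliases bestEpoch,TrainingHistory-method
setMethod("bestEpoch", "TrainingHistory", function(x) x@bestEpoch)

#' @rdname accessors
#' @aliases stoppedEpoch,TrainingHistory-method
setMethod("stoppedEpoch", "TrainingHistory", function(x) x@stoppedEpoch)

#' @rdname accessors
#' @aliases confusion,MetricsReport-method
setMethod("confusion", "MetricsReport", function(x) x@confusionMatrix)

#' @rdname accessors
#' @aliases perClassMetrics,MetricsReport-method
setMethod("perClassMetrics", "MetricsReport", function(x) x@perClass)

#' @rdname accessors
#' @aliases macroMetrics,MetricsReport-method
setMethod("macroMetrics", "MetricsReport", function(x) x@macro)

#' @rdname accessors
#' @aliases accuracy,MetricsReport-method
setMethod("accuracy", "MetricsReport", function(x) x@overallAccuracy)

#' @rdname accessors
#' @aliases saliencyValues,SaliencyMap-method
setMethod("saliencyValues", "SaliencyMap", function(x) x@values)

setMethod("show", "ArchitectureSpec", function(object) {
  cat("ArchitectureSpec\n")
  cat(sprintf("  input: %dx%dx%d\n", object@inputHeight, object@inputWidth,
              object@inputChannels))
  cat(sprintf("  stem: %d filters | blocks: %s | attention: %s\n",
              object@stemFilters, paste(object@blockChannels, collapse = "/"),
              paste(object@attentionPlan, collapse = ", ")))
  cat(sprintf("  head: %s units, dropout %.2f | classes: %d | SE r=%d\n",
              paste(object@denseUnits, collapse = " -> "), object@dropoutRate,
              object@numClasses, object@seReduction))
})

setMethod("show", "FundusDataset", function(object) {
  d <- dim(object@images)
  cat(sprintf("FundusDataset: %d images (%dx%dx%d), %d classes\n",
              d[4], d[1], d[2], d[3], length(object@classNames)))
  tab <- table(factor(object@classNames[object@labels + 1L],
                      levels = object@classNames))
  print(tab)
})

setMethod("show", "FundusModel", function(object) {
  cat(sprintf("FundusModel: %d layers (input %dx%dx%d, %d classes)\n",
              length(object@layers), object@spec@inputHeight,
              object@spec@inputWidth, object@spec@inputChannels,
              object@spec@numClasses))
  ps <- countParameters(object)
  cat(sprintf("  parameters: %s trainable, %s non-trainable\n",
              format(ps@trainable, big.mark = ","),
              format(ps@nonTrainable, big.mark = ",")))
})

setMethod("show", "ParamSummary", function(object) {
  cat("Parameter summary\n")
  df <- object@perLayer
  df$layer <- format(df$layer, width = max(nchar(df$layer)))
  print(df, row.names = FALSE)
  cat(sprintf("Trainable     %12s  %.2f MB\n",
              format(object@trainable, big.mark = ","), object@trainableMem))
  cat(sprintf("Non-trainable %12s  %.2f KB\n",
              format(object@nonTrainable, big.mark = ","), object@nonTrainableMem))
  cat(sprintf("Total         %12s\n", format(object@total, big.mark = ",")))
})

setMethod("show", "TrainingHistory", function(object) {
  cat(sprintf("TrainingHistory: %d epochs (best %d, stopped %d)\n",
              nrow(object@records), object@bestEpoch, object@stoppedEpoch))
  if (nrow(object@records)) {
    last <- object@records[nrow(object@records), ]
    cat(sprintf("  final: train %.4f/%.3f, val %.4f/%.3f, lr %.2e\n",
                last$train_loss, last$train_acc, last$val_loss, last$val_acc,
                last$lr))
  }
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: accuracy %.3f | macro P/R/F1 %.3f/%.3f/%.3f\n",
              object@overallAccuracy, object@macro["precision"],
              object@macro["recall"], object@macro["f1"]))
  df <- object@perClass
  df$precision <- round(df$precision, 3)
  df$recall <- round(df$recall, 3)
  df$f1 <- round(df$f1, 3)
  print(df, row.names = FALSE)
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf("SaliencyMap (%s): %dx%d, layer %s, class %d, peak %.3f\n",
              object@method, nrow(object@values), ncol(object@values),
              object@sourceLayer, object@classIndex, max(object@values)))
})
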
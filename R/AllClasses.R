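#' Architecture specification for the attention-augmented CNN
#'
#' Declarative description of the network: input geometry, stem width, the
#' channel progression of the four feature blocks, where each attention
#' mechanism sits, the squeeze-and-excitation reduction ratio, the widths of
#' the dense classification head, the head dropout rate and the number of
#' output classes. The default values describe the full-scale screening
#' network (stem 64, blocks 128/256/512/1024, head 1024 then 512 units,
#' dropout 0.5, ten classes); see \code{\link{defaultArchitecture}}.
#'
#' @slot inputHeight,inputWidth Input image size in pixels.
#' @slot inputChannels Number of input channels (3 for RGB).
#' @slot stemFilters Filters of the initial 3x3 convolution.
#' @slot blockChannels Integer vector of length 4: output channels of the
#'   four feature blocks.
#' @slot seReduction Reduction ratio r of the squeeze-and-excitation
#'   bottleneck.
#' @slot denseUnits Integer vector: widths of the hidden dense layers.
#' @slot dropoutRate Dropout probability applied after each hidden dense
#'   layer.
#' @slot numClasses Number of output classes.
#' @slot attentionPlan Character vector of length 4, one of \code{"se"},
#'   \code{"gc"}, \code{"residual"} per block.
#' @name ArchitectureSpec-class
#' @rdname ArchitectureSpec-class
#' @exportClass ArchitectureSpec
setClass("ArchitectureSpec",
  representation(
    inputHeight = "integer", inputWidth = "integer", inputChannels = "integer",
    stemFilters = "integer", blockChannels = "integer", seReduction = "integer",
    denseUnits = "integer", dropoutRate = "numeric", numClasses = "integer",
    attentionPlan = "character"
  )
)

setValidity("ArchitectureSpec", function(object) {
  msg <- character(0)
  cnt <- c(object@inputHeight, object@inputWidth, object@inputChannels,
           object@stemFilters, object@blockChannels, object@seReduction,
           object@denseUnits, object@numClasses)
  if (any(cnt <= 0L)) msg <- c(msg, "all counts must be positive")
  if (length(object@blockChannels) != 4L)
    msg <- c(msg, "blockChannels must have length 4")
  if (length(object@attentionPlan) != 4L ||
      !all(object@attentionPlan %in% c("se", "gc", "residual")))
    msg <- c(msg, "attentionPlan must be 4 tags from {se, gc, residual}")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  if (!length(msg)) {  # SE width checks only make sense on a valid shape
    for (i in seq_len(4L)) {
      if (object@attentionPlan[i] == "se" &&
          object@blockChannels[i] %/% object@seReduction < 1L)
        msg <- c(msg, sprintf(
          "block %d: SE reduced width floor(%d/%d) < 1", i,
          object@blockChannels[i], object@seReduction))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Fundus image dataset bundle
#'
#' Container for a loaded (or generated) image classification dataset:
#' an image stack, integer labels, the ordered class vocabulary and a file
#' manifest. Images are stored as an (H, W, channels, n) array with values
#' in [0, 1]; labels are 0-based indices into \code{classNames}, which is
#' kept in sorted (lexicographic) order so label indices are stable.
#'
#' @slot images Numeric array (H, W, C, n) in [0, 1].
#' @slot labels Integer vector of 0-based class indices, length n.
#' @slot classNames Ordered character vector of class names.
#' @slot manifest data.frame with one row per image (path, class_name,
#'   class_index and optionally split).
#' @name FundusDataset-class
#' @rdname FundusDataset-class
#' @exportClass FundusDataset
setClass("FundusDataset",
  representation(images = "array", labels = "integer",
                 classNames = "character", manifest = "data.frame")
)

setValidity("FundusDataset", function(object) {
  msg <- character(0)
  d <- dim(object@images)
  if (length(d) != 4L) msg <- c(msg, "images must be a 4-d array (H, W, C, n)")
  else if (d[4] != length(object@labels))
    msg <- c(msg, "number of images and labels differ")
  if (length(object@labels) &&
      (min(object@labels) < 0L ||
       max(object@labels) >= length(object@classNames)))
    msg <- c(msg, "labels must lie in [0, numberOfClasses)")
  rng <- suppressWarnings(range(object@images))
  if (length(object@images) && (rng[1] < 0 || rng[2] > 1))
    msg <- c(msg, "image values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Built model handle
#'
#' A built network: the architecture specification, an ordered named layer
#' registry (each entry holding its trainable parameter arrays and, for batch
#' normalization, the non-trainable moving statistics), and the seed used for
#' weight initialization. Layer outputs can be tapped by name for class
#' activation mapping; see \code{\link{tapPoints}}.
#'
#' @slot spec The \linkS4class{ArchitectureSpec} the model was built from.
#' @slot layers Ordered named list of layer records.
#' @slot seed Integer seed used for initialization.
#' @name FundusModel-class
#' @rdname FundusModel-class
#' @exportClass FundusModel
setClass("FundusModel",
  representation(spec = "ArchitectureSpec", layers = "list", seed = "integer")
)

setValidity("FundusModel", function(object) {
  nms <- vapply(object@layers, function(l) l$name, character(1))
  if (anyDuplicated(nms)) "layer names must be unique" else TRUE
})

#' Parameter accounting summary
#'
#' Exact integer accounting of a built model's parameters, layer by layer,
#' with memory footprints at 4 bytes per parameter (trainable in MiB,
#' non-trainable in KiB, both rounded to 2 decimals). Non-trainable
#' parameters are the batch-normalization moving statistics.
#'
#' @slot trainable,nonTrainable,total Integer parameter counts.
#' @slot trainableMem Trainable memory footprint in MiB.
#' @slot nonTrainableMem Non-trainable memory footprint in KiB.
#' @slot perLayer data.frame (layer, trainable, non_trainable).
#' @name ParamSummary-class
#' @rdname ParamSummary-class
#' @exportClass ParamSummary
setClass("ParamSummary",
  representation(trainable = "numeric", nonTrainable = "numeric",
                 total = "numeric", trainableMem = "numeric",
                 nonTrainableMem = "numeric", perLayer = "data.frame")
)

setValidity("ParamSummary", function(object) {
  msg <- character(0)
  if (object@total != object@trainable + object@nonTrainable)
    msg <- c(msg, "total must equal trainable + nonTrainable")
  if (sum(object@perLayer$trainable) != object@trainable ||
      sum(object@perLayer$non_trainable) != object@nonTrainable)
    msg <- c(msg, "per-layer sums must equal the totals")
  if (length(msg)) msg else TRUE
})

#' Training history
#'
#' Per-epoch record of a training run: losses, accuracies and the learning
#' rate, together with the best epoch (by the checkpoint monitor) and the
#' epoch at which training stopped.
#'
#' @slot records data.frame with columns epoch, lr, train_loss, train_acc,
#'   val_loss, val_acc.
#' @slot bestEpoch,stoppedEpoch Integer epoch indices (1-based).
#' @name TrainingHistory-class
#' @rdname TrainingHistory-class
#' @exportClass TrainingHistory
setClass("TrainingHistory",
  representation(records = "data.frame", bestEpoch = "integer",
                 stoppedEpoch = "integer")
)

setValidity("TrainingHistory", function(object) {
  msg <- character(0)
  if (nrow(object@records) > 0) {
    lr <- object@records$lr
    if (any(diff(lr) > 1e-15)) msg <- c(msg, "learning rate must be non-increasing")
    if (object@bestEpoch > object@stoppedEpoch)
      msg <- c(msg, "bestEpoch must not exceed stoppedEpoch")
  }
  if (length(msg)) msg else TRUE
})

#' Classification metrics report
#'
#' Confusion matrix (rows = true class, columns = predicted class) with
#' per-class precision, recall, F1 and support, their unweighted macro
#' averages, and overall accuracy (trace over total).
#'
#' @slot confusionMatrix Integer N x N matrix with class-name dimnames.
#' @slot perClass data.frame (class, precision, recall, f1, support).
#' @slot macro Named numeric vector (precision, recall, f1).
#' @slot overallAccuracy Numeric scalar in [0, 1].
#' @name MetricsReport-class
#' @rdname MetricsReport-class
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(confusionMatrix = "matrix", perClass = "data.frame",
                 macro = "numeric", overallAccuracy = "numeric")
)

setValidity("MetricsReport", function(object) {
  msg <- character(0)
  if (any(object@confusionMatrix < 0)) msg <- c(msg, "confusion counts must be >= 0")
  vals <- c(object@perClass$precision, object@perClass$recall,
            object@perClass$f1, object@macro, object@overallAccuracy)
  if (any(vals < -1e-12 | vals > 1 + 1e-12)) msg <- c(msg, "metrics must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Class-conditional saliency map
#'
#' Normalized Grad-CAM or Grad-CAM++ heatmap at input resolution, with the
#' tap layer, target class and method recorded. Values lie in [0, 1]; an
#' all-zero map encodes the no-evidence case (class score constant with
#' respect to the tapped activations).
#'
#' @slot values Numeric H x W matrix in [0, 1].
#' @slot sourceLayer Name of the tapped convolutional layer.
#' @slot classIndex 0-based target class index.
#' @slot method Either "gradcam" or "gradcampp".
#' @name SaliencyMap-class
#' @rdname SaliencyMap-class
#' @exportClass SaliencyMap
setClass("SaliencyMap",
  representation(values = "matrix", sourceLayer = "character",
                 classIndex = "integer", method = "character")
)

setValidity("SaliencyMap", function(object) {
  msg <- character(0)
  if (!object@method %in% c("gradcam", "gradcampp"))
    msg <- c(msg, "method must be gradcam or gradcampp")
  rng <- range(object@values)
  if (rng[1] < 0 || rng[2] > 1) msg <- c(msg, "saliency values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
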
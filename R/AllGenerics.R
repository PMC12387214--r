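#' @include AllClasses.R
NULL

#' Accessors for fundusnet S4 containers
#'
#' Small accessor generics used across the package's containers:
#' \code{images}, \code{labels}, \code{classNames} and \code{manifest} for
#' \linkS4class{FundusDataset}; \code{historyTable}, \code{bestEpoch} and
#' \code{stoppedEpoch} for \linkS4class{TrainingHistory}; \code{confusion},
#' \code{perClassMetrics}, \code{macroMetrics} and \code{accuracy} for
#' \linkS4class{MetricsReport}; \code{saliencyValues} for
#' \linkS4class{SaliencyMap}.
#'
#' @param x An object of the documented class.
#' @return The slot content (see the class documentation).
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @rdname accessors
#' @param object,... For the \code{labels} method (whose generic comes from
#'   base R): the object and ignored extra arguments.
#' @export
setGeneric("labels")

#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname accessors
#' @export
setGeneric("historyTable", function(x) standardGeneric("historyTable"))

#' @rdname accessors
#' @export
setGeneric("bestEpoch", function(x) standardGeneric("bestEpoch"))

#' @rdname accessors
#' @export
setGeneric("stoppedEpoch", function(x) standardGeneric("stoppedEpoch"))

#' @rdname accessors
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' @rdname accessors
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @rdname accessors
#' @export
setGeneric("macroMetrics", function(x) standardGeneric("macroMetrics"))

#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname accessors
#' @export
setGeneric("saliencyValues", function(x) standardGeneric("saliencyValues"))

#' Count model parameters
#'
#' @param model A \linkS4class{FundusModel}.
#' @return A \linkS4class{ParamSummary}.
#' @export
setGeneric("countParameters", function(model) standardGeneric("countParameters"))
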
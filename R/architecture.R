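#' @include AllClasses.R
NULL

#' Construct an architecture specification
#'
#' Builds an \linkS4class{ArchitectureSpec}. Defaults describe the full-scale
#' network: 150x150x3 input, a 64-filter stem, four feature blocks widening
#' to 128/256/512/1024 channels with squeeze-and-excitation attention on
#' blocks 1 and 3, global-context attention on block 2 and a residual block
#' as block 4, followed by a global-average-pooling head with dense layers of
#' 1024 and 512 units (dropout 0.5) and a softmax over 10 classes.
#'
#' @param inputHeight,inputWidth,inputChannels Input geometry in pixels /
#'   channels.
#' @param stemFilters Filters of the initial 3x3 convolution.
#' @param blockChannels Integer vector of length 4 (block output channels).
#' @param seReduction Squeeze-and-excitation reduction ratio r.
#' @param denseUnits Hidden dense layer widths of the classification head.
#' @param dropoutRate Head dropout probability in [0, 1).
#' @param numClasses Number of output classes.
#' @param attentionPlan Per-block attention tags ("se", "gc" or "residual").
#' @return A validated \linkS4class{ArchitectureSpec}.
#' @examples
#' spec <- architectureSpec(numClasses = 2L)
#' spec
#' @export
architectureSpec <- function(inputHeight = 150L, inputWidth = 150L,
                             inputChannels = 3L, stemFilters = 64L,
                             blockChannels = c(128L, 256L, 512L, 1024L),
                             seReduction = 16L,
                             denseUnits = c(1024L, 512L),
                             dropoutRate = 0.5, numClasses = 10L,
                             attentionPlan = c("se", "gc", "se", "residual")) {
  new("ArchitectureSpec",
      inputHeight = as.integer(inputHeight), inputWidth = as.integer(inputWidth),
      inputChannels = as.integer(inputChannels),
      stemFilters = as.integer(stemFilters),
      blockChannels = as.integer(blockChannels),
      seReduction = as.integer(seReduction),
      denseUnits = as.integer(denseUnits), dropoutRate = dropoutRate,
      numClasses = as.integer(numClasses), attentionPlan = attentionPlan)
}

#' Default full-scale architecture
#'
#' The screening network as deployed: roughly 16.6 million parameters.
#' @return An \linkS4class{ArchitectureSpec}.
#' @export
defaultArchitecture <- function() architectureSpec()

#' Reduced-width architecture for desk-scale experiments
#'
#' Same topology as \code{\link{defaultArchitecture}} (stem + SE/GC/SE
#' attention blocks + residual block + two-layer dense head) at a fraction of
#' the width, for fast CPU training on synthetic fixtures.
#'
#' @param inputSize Square input size in pixels (default 64).
#' @param numClasses Number of classes (default 10).
#' @return An \linkS4class{ArchitectureSpec}.
#' @export
reducedArchitecture <- function(inputSize = 64L, numClasses = 10L) {
  architectureSpec(inputHeight = inputSize, inputWidth = inputSize,
                   stemFilters = 8L, blockChannels = c(16L, 32L, 64L, 128L),
                   seReduction = 4L, denseUnits = c(128L, 64L),
                   numClasses = numClasses)
}

#' Spatial size trace through the network
#'
#' Applies the 2x2 stride-2 floor-semantics max-pool arithmetic to the input
#' size: one pool after the stem and one after each of the four blocks.
#'
#' @param spec An \linkS4class{ArchitectureSpec}.
#' @return Integer vector of spatial sizes, starting at the input size, one
#'   entry per pooling stage (length 6).
#' @examples
#' spatialTrace(defaultArchitecture()) # 150 75 37 18 9 4
#' @export
spatialTrace <- function(spec) {
  s <- spec@inputHeight
  out <- s
  for (i in 1:5) {
    s <- s %/% 2L
    out <- c(out, s)
  }
  out
}
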
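# Shared fixtures: tiny architectures, hand-assembled toy models for CAM
# checks, and small synthetic datasets. Everything is built in code at test
# time; no stored binary fixtures.

tinySpec <- function(numClasses = 3L, inputSize = 32L) {
  architectureSpec(inputHeight = inputSize, inputWidth = inputSize,
                   stemFilters = 4L, blockChannels = c(4L, 6L, 8L, 10L),
                   seReduction = 2L, denseUnits = c(12L, 8L),
                   dropoutRate = 0, numClasses = numClasses)
}

# assemble a FundusModel from an explicit layer list (internal constructors),
# so CAM tests can use models with analytically known behavior
toyModel <- function(layers, inputSize, numClasses) {
  names(layers) <- vapply(layers, function(l) l$name, character(1))
  spec <- architectureSpec(inputHeight = inputSize, inputWidth = inputSize,
                           numClasses = numClasses)
  new("FundusModel", spec = spec, layers = layers, seed = 1L)
}

# toy: single-channel conv tap, class-1 score = sum_ij A_ij
# (gap averages, so the output weight HW restores the sum)
sumScoreToyModel <- function(inputSize = 6L, seed = 1L) {
  set.seed(seed)
  conv <- fundusnet:::mkConv("tap_conv", 3, 3, 1, 1)
  gap <- fundusnet:::mkSimple("gap", "gap")
  out <- fundusnet:::mkDense("output_dense", 1L, 2L)
  out$params$W[] <- c(0, inputSize^2)  # class 0: 0, class 1: HW
  out$params$b[] <- 0
  sm <- fundusnet:::mkSimple("softmax", "softmax")
  toyModel(list(conv, gap, out, sm), inputSize, 2L)
}

# small balanced synthetic dataset (in memory); cached per session
syntheticFixture <- local({
  cache <- list()
  function(perClass = 12L, size = 48L, seed = 3L) {
    key <- paste(perClass, size, seed)
    if (is.null(cache[[key]])) {
      cfg <- generatorConfig(
        counts = stats::setNames(rep(as.integer(perClass), 10L),
                                 fundusnet:::fundusClassNames()),
        imageSize = size, seed = seed)
      cache[[key]] <<- generateFundusArrays(cfg)
    }
    cache[[key]]
  }
})

expect_all_finite <- function(x) testthat::expect_true(all(is.finite(x)))
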
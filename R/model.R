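#' @include AllClasses.R AllGenerics.R architecture.R layers.R
NULL

mkConv <- function(name, kh, kw, cin, cout) {
  list(name = name, type = "conv",
       params = list(k = heInit(c(kh, kw, cin, cout), kh * kw * cin),
                     b = numeric(cout)),
       state = list(), cfg = list())
}

mkDwConv <- function(name, kh, kw, c) {
  list(name = name, type = "dwconv",
       params = list(k = heInit(c(kh, kw, c), kh * kw), b = numeric(c)),
       state = list(), cfg = list())
}

mkBN <- function(name, c) {
  list(name = name, type = "bn",
       params = list(gamma = rep(1, c), beta = numeric(c)),
       state = list(movMean = numeric(c), movVar = rep(1, c)), cfg = list())
}

mkSE <- function(name, c, r) {
  cr <- c %/% r
  if (cr < 1L)
    stop("SE block '", name, "': reduced width floor(", c, "/", r, ") < 1")
  list(name = name, type = "se",
       params = list(W1 = heInit(c(cr, c), c), b1 = numeric(cr),
                     W2 = heInit(c(c, cr), cr), b2 = numeric(c)),
       state = list(), cfg = list())
}

mkGC <- function(name, c) {
  list(name = name, type = "gc",
       params = list(Wg = heInit(c(c, c), c), bg = numeric(c)),
       state = list(), cfg = list())
}

mkResBlock <- function(name, cin, f) {
  list(name = name, type = "resblock",
       params = list(
         k1 = heInit(c(3, 3, cin, f), 9 * cin), cb1 = numeric(f),
         g1 = rep(1, f), be1 = numeric(f),
         k2 = heInit(c(3, 3, f, f), 9 * f), cb2 = numeric(f),
         g2 = rep(1, f), be2 = numeric(f),
         ks = heInit(c(1, 1, cin, f), cin), cbs = numeric(f),
         gs = rep(1, f), bes = numeric(f)),
       state = list(m1 = numeric(f), v1 = rep(1, f), m2 = numeric(f),
                    v2 = rep(1, f), ms = numeric(f), vs = rep(1, f)),
       cfg = list())
}

mkDense <- function(name, nin, nout) {
  list(name = name, type = "dense",
       params = list(W = heInit(c(nout, nin), nin), b = numeric(nout)),
       state = list(), cfg = list())
}

mkSimple <- function(name, type, cfg = list()) {
  list(name = name, type = type, params = list(), state = list(), cfg = cfg)
}

#' Build the attention-augmented CNN
#'
#' Assembles the network described by an \linkS4class{ArchitectureSpec} into
#' an ordered layer registry: a 3x3 convolution stem with batch
#' normalization, ReLU and 2x2 max-pooling; four feature blocks (depthwise
#' separable convolution + channel attention for "se"/"gc" blocks, a
#' two-convolution residual block with 1x1-projected skip for "residual"),
#' each followed by 2x2 max-pooling; global average pooling; and a dense
#' head with ReLU, dropout and a softmax output. Every convolution and dense
#' layer carries a bias; batch normalization follows the stem convolution,
#' both halves of each depthwise separable convolution and all three
#' convolutions of the residual block. Weights use He (fan-in) initialization
#' with the given seed; biases start at zero.
#'
#' @param spec An \linkS4class{ArchitectureSpec}.
#' @param seed Integer seed for weight initialization.
#' @return A \linkS4class{FundusModel}.
#' @examples
#' m <- buildModel(reducedArchitecture(inputSize = 32L), seed = 1L)
#' countParameters(m)
#' @export
buildModel <- function(spec, seed = 1L) {
  stopifnot(is(spec, "ArchitectureSpec"))
  validObject(spec)
  tr <- spatialTrace(spec)
  if (any(tr < 1L))
    stop("input size ", spec@inputHeight,
         " collapses to zero after the five 2x2 pools (trace: ",
         paste(tr, collapse = " "), "); use at least 32 pixels")
  set.seed(seed)
  L <- list()
  add <- function(l) L[[length(L) + 1L]] <<- l
  add(mkConv("stem_conv", 3, 3, spec@inputChannels, spec@stemFilters))
  add(mkBN("stem_bn", spec@stemFilters))
  add(mkSimple("stem_relu", "relu"))
  add(mkSimple("stem_pool", "maxpool"))
  cin <- spec@stemFilters
  for (i in seq_len(4L)) {
    f <- spec@blockChannels[i]
    att <- spec@attentionPlan[i]
    pre <- sprintf("block%d", i)
    if (att == "residual") {
      add(mkResBlock(paste0(pre, "_res"), cin, f))
    } else {
      add(mkDwConv(paste0(pre, "_dw"), 3, 3, cin))
      add(mkBN(paste0(pre, "_dw_bn"), cin))
      add(mkSimple(paste0(pre, "_dw_relu"), "relu"))
      add(mkConv(paste0(pre, "_pw"), 1, 1, cin, f))
      add(mkBN(paste0(pre, "_pw_bn"), f))
      add(mkSimple(paste0(pre, "_pw_relu"), "relu"))
      if (att == "se") add(mkSE(paste0(pre, "_se"), f, spec@seReduction))
      else add(mkGC(paste0(pre, "_gc"), f))
    }
    add(mkSimple(paste0(pre, "_pool"), "maxpool"))
    cin <- f
  }
  add(mkSimple("gap", "gap"))
  nin <- cin
  for (j in seq_along(spec@denseUnits)) {
    u <- spec@denseUnits[j]
    add(mkDense(sprintf("fc%d", j), nin, u))
    add(mkSimple(sprintf("fc%d_relu", j), "relu"))
    add(mkSimple(sprintf("fc%d_drop", j), "dropout",
                 cfg = list(rate = spec@dropoutRate)))
    nin <- u
  }
  add(mkDense("output_dense", nin, spec@numClasses))
  add(mkSimple("softmax", "softmax"))
  names(L) <- vapply(L, function(l) l$name, character(1))
  new("FundusModel", spec = spec, layers = L, seed = as.integer(seed))
}

layerIndex <- function(model, name) {
  idx <- match(name, names(model@layers))
  if (is.na(idx)) stop("no layer named '", name, "'")
  idx
}

#' Run the network forward
#'
#' Low-level forward pass. \code{x} is an (H, W, C, B) image batch in [0, 1]
#' (or, when \code{fromLayer} is given, the output of that layer, from which
#' computation resumes). In inference mode dropout is disabled and batch
#' normalization uses its moving statistics; in training mode batch
#' statistics are used and the moving statistics are updated in the returned
#' model.
#'
#' @param model A \linkS4class{FundusModel}.
#' @param x Input array (see above).
#' @param training Logical; training-mode semantics for BN and dropout.
#' @param keepCache Keep per-layer caches and activations (needed for
#'   backward passes and CAM taps).
#' @param fromLayer Optional layer name: treat \code{x} as that layer's
#'   output and resume from the next layer.
#' @return List with \code{probs} (B x N matrix), \code{logits} (B x N),
#'   \code{acts}/\code{caches} (named, when \code{keepCache}), and
#'   \code{model} (with updated BN state when \code{training}).
#' @export
modelForward <- function(model, x, training = FALSE, keepCache = FALSE,
                         fromLayer = NULL) {
  L <- model@layers
  start <- if (is.null(fromLayer)) 1L else layerIndex(model, fromLayer) + 1L
  caches <- if (keepCache) vector("list", length(L)) else NULL
  acts <- if (keepCache) vector("list", length(L)) else NULL
  logits <- NULL
  for (li in seq(start, length(L))) {
    r <- layerForward(L[[li]], x, training)
    if (keepCache) {
      caches[li] <- list(r$cache)  # list-assign: a NULL cache must not shrink
      acts[[li]] <- r$y
    }
    if (training) L[[li]] <- r$layer
    if (L[[li]]$name == "output_dense") logits <- r$y
    x <- r$y
  }
  if (keepCache) names(caches) <- names(acts) <- names(L)
  model@layers <- L
  list(probs = t(x), logits = if (!is.null(logits)) t(logits) else NULL,
       acts = acts, caches = caches, model = model)
}

# Backward pass from a gradient with respect to the logits (output_dense
# output, N x B). Stops after computing the gradient w.r.t. stopLayer's
# output when stopLayer is given. Returns per-layer parameter gradients and
# the terminal gradient.
modelBackward <- function(model, caches, dLogits, training = FALSE,
                          stopLayer = NULL) {
  L <- model@layers
  outIdx <- layerIndex(model, "output_dense")
  stopIdx <- if (is.null(stopLayer)) 0L else layerIndex(model, stopLayer)
  grads <- list()
  d <- dLogits
  li <- outIdx
  while (li > stopIdx) {
    r <- layerBackward(L[[li]], caches[[li]], d, training)
    if (length(r$grads)) grads[[L[[li]]$name]] <- r$grads
    d <- r$dx
    li <- li - 1L
  }
  list(grads = grads, dOut = d)
}

#' Forward inference on an image batch
#'
#' Inference-mode forward pass: dropout off, batch normalization on moving
#' statistics. Rows of the returned matrix are softmax probability
#' distributions (they sum to 1).
#'
#' @param model A \linkS4class{FundusModel}.
#' @param batch (H, W, C, B) array of images in [0, 1], or a single (H, W, C)
#'   image.
#' @return B x N probability matrix.
#' @export
forward <- function(model, batch) {
  if (length(dim(batch)) == 3L) dim(batch) <- c(dim(batch), 1L)
  d <- dim(batch)
  sp <- model@spec
  if (d[1] != sp@inputHeight || d[2] != sp@inputWidth ||
      d[3] != sp@inputChannels)
    stop(sprintf("expected %dx%dx%d input, got %dx%dx%d",
                 sp@inputHeight, sp@inputWidth, sp@inputChannels,
                 d[1], d[2], d[3]))
  modelForward(model, batch, training = FALSE)$probs
}

#' Names of CAM tap points
#'
#' Layers whose outputs retain spatial structure and can be tapped for class
#' activation mapping. The default CAM layer is the pre-pool output of the
#' last (residual) block, which has the highest spatial resolution among the
#' deepest feature maps.
#'
#' @param model A \linkS4class{FundusModel}.
#' @return Character vector of layer names.
#' @export
tapPoints <- function(model) {
  spatial <- c("conv", "dwconv", "bn", "relu", "maxpool", "se", "gc",
               "resblock")
  nms <- names(model@layers)
  nms[vapply(model@layers, function(l) l$type %in% spatial, logical(1))]
}

#' @rdname countParameters
#' @aliases countParameters,FundusModel-method
#' @export
setMethod("countParameters", "FundusModel", function(model) {
  per <- lapply(model@layers, function(l) {
    data.frame(layer = l$name,
               trainable = sum(vapply(l$params, length, numeric(1)), 0),
               non_trainable = sum(vapply(l$state, length, numeric(1)), 0))
  })
  df <- do.call(rbind, per)
  rownames(df) <- NULL
  tr <- sum(df$trainable)
  nt <- sum(df$non_trainable)
  new("ParamSummary", trainable = tr, nonTrainable = nt, total = tr + nt,
      trainableMem = round(tr * 4 / 1024^2, 2),
      nonTrainableMem = round(nt * 4 / 1024, 2), perLayer = df)
})

#' Serialize / restore a model
#'
#' \code{saveModel} writes the weights in R's native serialization alongside
#' a JSON sidecar recording the architecture specification and the per-layer
#' parameter summary for cross-implementation comparison; \code{loadModel}
#' restores the model from the checkpoint.
#'
#' @param model A \linkS4class{FundusModel}.
#' @param path Checkpoint path (the sidecar gets extension .json).
#' @return \code{saveModel}: the sidecar path, invisibly. \code{loadModel}:
#'   a \linkS4class{FundusModel}.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  ps <- countParameters(model)
  sp <- model@spec
  sidecar <- list(
    architecture = list(
      input = c(sp@inputHeight, sp@inputWidth, sp@inputChannels),
      stem_filters = sp@stemFilters, block_channels = sp@blockChannels,
      se_reduction = sp@seReduction, dense_units = sp@denseUnits,
      dropout_rate = sp@dropoutRate, num_classes = sp@numClasses,
      attention_plan = sp@attentionPlan),
    parameters = list(trainable = ps@trainable,
                      non_trainable = ps@nonTrainable, total = ps@total,
                      per_layer = ps@perLayer))
  side <- paste0(sub("\\.[^.]*$", "", path), ".json")
  jsonlite::write_json(sidecar, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  stopifnot(is(m, "FundusModel"))
  m
}
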
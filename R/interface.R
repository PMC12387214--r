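#' @include AllClasses.R model.R training.R evaluation.R cam.R synthetic.R
NULL

runConfigDefaults <- function() {
  list(
    seed = 1L,
    paths = list(data_dir = "data/fundus", run_dir = "runs/run"),
    architecture = list(
      input_size = 150L, stem_filters = 64L,
      block_channels = c(128L, 256L, 512L, 1024L), se_reduction = 16L,
      dense_units = c(1024L, 512L), dropout_rate = 0.5, num_classes = 10L),
    smote = list(enabled = TRUE, k_neighbors = 5L, target = "majority",
                 search_downscale = NULL),
    split = list(fractions = c(0.70, 0.15, 0.15), split_first = FALSE),
    augment = list(rotation_deg = 20, shift_frac = 0.10, shear_frac = 0.10,
                   zoom_frac = 0.10, horizontal_flip = TRUE),
    training = list(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                    batch_size = 32L, max_epochs = 50L, plateau_factor = 0.5,
                    plateau_patience = 5L, min_lr = 1e-6,
                    early_stop_patience = 15L, l2_lambda = 0.01,
                    l2_scope = "head"),
    generator = list(counts = as.list(defaultClassCounts()),
                     image_size = 150L, overwrite = FALSE),
    explain = list(layer = "block4_res", alpha = 0.4, num_examples = 5L)
  )
}

mergeConfig <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    dv <- defaults[[key]]
    uv <- user[[key]]
    if (is.list(dv) && !key %in% c("counts")) {
      if (!is.list(uv)) stop("configuration key ", full, " must be a section")
      defaults[[key]] <- mergeConfig(dv, uv, full)
    } else {
      # coerce to the default's type so configs round-trip losslessly;
      # list-assign so NULL values (e.g. unset options) keep their key
      defaults[key] <- list(
        if (is.integer(dv)) as.integer(unlist(uv))
        else if (is.numeric(dv)) as.numeric(unlist(uv))
        else if (is.logical(dv)) as.logical(unlist(uv))
        else if (is.list(dv)) lapply(uv, as.integer)
        else if (is.null(dv)) uv
        else unlist(uv))
    }
  }
  defaults
}

validateRunConfig <- function(cfg) {
  chk <- function(ok, key) if (!ok) stop("invalid value for ", key)
  chk(cfg$training$learning_rate > 0, "training.learning_rate")
  chk(cfg$training$batch_size >= 1, "training.batch_size")
  chk(cfg$training$l2_lambda >= 0, "training.l2_lambda")
  chk(cfg$training$plateau_factor > 0 && cfg$training$plateau_factor < 1,
      "training.plateau_factor")
  chk(cfg$training$min_lr <= cfg$training$learning_rate, "training.min_lr")
  chk(cfg$architecture$dropout_rate >= 0 && cfg$architecture$dropout_rate < 1,
      "architecture.dropout_rate")
  chk(abs(sum(cfg$split$fractions) - 1) < 1e-9, "split.fractions")
  chk(cfg$smote$k_neighbors >= 1, "smote.k_neighbors")
  chk(cfg$generator$image_size >= 32, "generator.image_size")
  chk(all(unlist(cfg$generator$counts) >= 2), "generator.counts")
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) run configuration, fills every unspecified key with
#' the pipeline defaults (Adam learning rate 1e-4, batch 32, lambda 0.01,
#' dropout 0.5, 70/15/15 split, the full-scale architecture and the default
#' generator counts), rejects unknown keys and validates values, naming the
#' offending key in errors. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a YAML/JSON file.
#' @return A validated nested list of class \code{"RunConfig"}.
#' @export
loadRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- mergeConfig(runConfigDefaults(), user)
  structure(validateRunConfig(cfg), class = "RunConfig")
}

#' @rdname loadRunConfig
#' @param config A \code{"RunConfig"} to write.
#' @export
saveRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stageArchitecture <- function(cfg) {
  a <- cfg$architecture
  architectureSpec(inputHeight = a$input_size, inputWidth = a$input_size,
                   stemFilters = a$stem_filters,
                   blockChannels = unlist(a$block_channels),
                   seReduction = a$se_reduction,
                   denseUnits = unlist(a$dense_units),
                   dropoutRate = a$dropout_rate, numClasses = a$num_classes)
}

requireArtifact <- function(path, hint) {
  if (!file.exists(path))
    stop("missing prerequisite: ", path, " (run the '", hint,
         "' stage first)")
  path
}

#' Run one pipeline stage
#'
#' Executes one stage of the screening workflow under
#' \code{config$paths$run_dir}, echoing the resolved configuration there:
#' \describe{
#'   \item{generate}{render the synthetic fundus tree into
#'     \code{paths$data_dir}}
#'   \item{prepare}{load the image tree, SMOTE-balance (then reshape back to
#'     images), stratified-split; writes prepared.rds, manifest.csv and
#'     split.json. The published order (balance, then split) is the default;
#'     set \code{split.split_first} to split before balancing instead.}
#'   \item{train}{build + train the model; writes history.csv, curves.png,
#'     checkpoint.rds and its JSON sidecar}
#'   \item{evaluate}{test-set metrics; writes metrics.json/.txt,
#'     confusion_matrix.csv and confusion.png}
#'   \item{explain}{per-image original / Grad-CAM / Grad-CAM++ panels and a
#'     prediction JSON for a few test images}
#'   \item{summary}{print the per-layer parameter table and totals}
#' }
#' Missing prerequisites raise an error naming the stage to run first.
#'
#' @param command One of generate, prepare, train, evaluate, explain, summary.
#' @param config A \code{"RunConfig"} (see \code{\link{loadRunConfig}}).
#' @param verbose Print progress.
#' @return Stage-dependent value, invisibly (e.g. the
#'   \linkS4class{ParamSummary} for \code{summary}).
#' @export
runStage <- function(command, config, verbose = FALSE) {
  command <- match.arg(command, c("generate", "prepare", "train", "evaluate",
                                  "explain", "summary"))
  runDir <- config$paths$run_dir
  dir.create(runDir, showWarnings = FALSE, recursive = TRUE)
  saveRunConfig(config, file.path(runDir, "config.yaml"))
  prepPath <- file.path(runDir, "prepared.rds")
  ckptPath <- file.path(runDir, "checkpoint.rds")

  if (command == "generate") {
    gc <- generatorConfig(
      counts = unlist(config$generator$counts)[order(names(config$generator$counts))],
      imageSize = config$generator$image_size, seed = config$seed)
    man <- generateFundusDataset(gc, config$paths$data_dir,
                                 force = isTRUE(config$generator$overwrite))
    return(invisible(man))
  }

  if (command == "summary") {
    ps <- countParameters(buildModel(stageArchitecture(config),
                                     seed = config$seed))
    show(ps)
    return(invisible(ps))
  }

  if (command == "prepare") {
    ds <- loadDataset(requireArtifact(config$paths$data_dir, "generate"),
                      targetSize = config$architecture$input_size)
    sc <- smoteConfig(kNeighbors = config$smote$k_neighbors,
                      targetCount = config$smote$target, seed = config$seed)
    imgs <- ds@images; labs <- ds@labels
    if (isTRUE(config$split$split_first)) {
      sp <- stratifiedSplit(labs, config$split$fractions, seed = config$seed)
      if (isTRUE(config$smote$enabled)) {
        bal <- smoteBalanceImages(imgs[, , , sp$train, drop = FALSE],
                                  labs[sp$train], sc,
                                  config$smote$search_downscale)
        nOld <- dim(imgs)[4]
        imgs <- array(c(imgs, bal$images[, , , -seq_along(sp$train)]),
                      c(dim(imgs)[1:3],
                        nOld + length(bal$labels) - length(sp$train)))
        labs <- c(labs, bal$labels[-seq_along(sp$train)])
        sp$train <- c(sp$train, seq(nOld + 1L, dim(imgs)[4]))
      }
    } else {
      if (isTRUE(config$smote$enabled)) {
        bal <- smoteBalanceImages(imgs, labs, sc,
                                  config$smote$search_downscale)
        imgs <- bal$images; labs <- bal$labels
      }
      sp <- stratifiedSplit(labs, config$split$fractions, seed = config$seed)
    }
    prepared <- list(images = imgs, labels = labs,
                     classNames = ds@classNames, split = sp)
    saveRDS(prepared, prepPath)
    utils::write.csv(ds@manifest, file.path(runDir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(sp[c("train", "val", "test")],
                         file.path(runDir, "split.json"))
    return(invisible(prepared))
  }

  if (command == "train") {
    prep <- readRDS(requireArtifact(prepPath, "prepare"))
    ds <- new("FundusDataset", images = prep$images, labels = prep$labels,
              classNames = prep$classNames,
              manifest = data.frame(path = character(0)))
    model <- buildModel(stageArchitecture(config), seed = config$seed)
    tc <- trainingConfig(
      learningRate = config$training$learning_rate,
      beta1 = config$training$beta1, beta2 = config$training$beta2,
      batchSize = config$training$batch_size,
      maxEpochs = config$training$max_epochs,
      plateauFactor = config$training$plateau_factor,
      plateauPatience = config$training$plateau_patience,
      minLr = config$training$min_lr,
      earlyStopPatience = config$training$early_stop_patience,
      l2Lambda = config$training$l2_lambda,
      l2Scope = config$training$l2_scope, seed = config$seed)
    ac <- augmentationConfig(
      rotationDeg = config$augment$rotation_deg,
      shiftFrac = config$augment$shift_frac,
      shearFrac = config$augment$shear_frac,
      zoomFrac = config$augment$zoom_frac,
      horizontalFlip = config$augment$horizontal_flip)
    fit <- trainModel(model, ds, prep$split, tc, ac, verbose = verbose)
    utils::write.csv(fit$history@records, file.path(runDir, "history.csv"),
                     row.names = FALSE)
    writeTrainingCurves(fit$history, file.path(runDir, "curves.png"))
    saveModel(fit$model, ckptPath)
    return(invisible(fit))
  }

  if (command == "evaluate") {
    prep <- readRDS(requireArtifact(prepPath, "prepare"))
    model <- loadModel(requireArtifact(ckptPath, "train"))
    ds <- new("FundusDataset", images = prep$images, labels = prep$labels,
              classNames = prep$classNames,
              manifest = data.frame(path = character(0)))
    rep <- evaluateModel(model, ds, prep$split$test)
    writeMetricsReport(rep, runDir)
    writeConfusionHeatmap(rep, file.path(runDir, "confusion.png"))
    return(invisible(rep))
  }

  # explain
  prep <- readRDS(requireArtifact(prepPath, "prepare"))
  model <- loadModel(requireArtifact(ckptPath, "train"))
  set.seed(config$seed)
  take <- prep$split$test[seq_len(min(config$explain$num_examples,
                                      length(prep$split$test)))]
  preds <- list()
  for (i in take) {
    img <- prep$images[, , , i]
    p <- forward(model, img)[1, ]
    cls <- which.max(p) - 1L
    cam <- gradCAM(model, img, cls, config$explain$layer)
    campp <- gradCAMpp(model, img, cls, config$explain$layer)
    panel <- abind3(img,
                    overlayHeatmap(img, cam, config$explain$alpha),
                    overlayHeatmap(img, campp, config$explain$alpha))
    png::writePNG(panel, file.path(runDir, sprintf("explain_%04d.png", i)))
    preds[[sprintf("image_%04d", i)]] <- list(
      true_class = prep$classNames[prep$labels[i] + 1L],
      predicted_class = prep$classNames[cls + 1L],
      probabilities = as.list(stats::setNames(p, prep$classNames)))
  }
  jsonlite::write_json(preds, file.path(runDir, "explain.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(preds)
}

# stack (H, W, 3) images vertically into one (3H, W, 3) panel
abind3 <- function(...) {
  imgs <- list(...)
  d <- dim(imgs[[1]])
  out <- array(0, c(d[1] * length(imgs), d[2], d[3]))
  for (i in seq_along(imgs))
    out[seq((i - 1) * d[1] + 1, i * d[1]), , ] <- imgs[[i]]
  out
}

writeTrainingCurves <- function(history, path) {
  rec <- history@records
  grDevices::png(path, width = 900, height = 420)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot(rec$epoch, rec$train_acc, type = "l", col = "steelblue",
                 ylim = range(c(rec$train_acc, rec$val_acc)),
                 xlab = "epoch", ylab = "accuracy", main = "Accuracy")
  graphics::lines(rec$epoch, rec$val_acc, col = "firebrick")
  graphics::legend("bottomright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::plot(rec$epoch, rec$train_loss, type = "l", col = "steelblue",
                 ylim = range(c(rec$train_loss, rec$val_loss)),
                 xlab = "epoch", ylab = "loss", main = "Loss")
  graphics::lines(rec$epoch, rec$val_loss, col = "firebrick")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(path)
}

writeConfusionHeatmap <- function(report, path) {
  cm <- confusion(report)
  grDevices::png(path, width = 640, height = 620)
  op <- graphics::par(mar = c(10, 10, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  n <- nrow(cm)
  graphics::image(seq_len(n), seq_len(n), t(cm[n:1, ]),
                  col = grDevices::hcl.colors(32, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Confusion matrix")
  graphics::axis(1, seq_len(n), colnames(cm), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(rownames(cm)), las = 2, cex.axis = 0.7)
  for (i in seq_len(n)) for (j in seq_len(n))
    graphics::text(j, n + 1 - i, cm[i, j], cex = 0.7)
  invisible(path)
}
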
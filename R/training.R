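#' @include AllClasses.R model.R augment.R
NULL

#' Training configuration
#'
#' Optimizer and schedule settings: Adam (learning rate 1e-4, beta1 0.9,
#' beta2 0.999), batch size 32, up to 50 epochs, reduce-on-plateau (factor
#' 0.5, patience 5, floor 1e-6) and early stopping (patience 15, restore best
#' weights), with an l2 penalty (lambda 0.01) on the hidden dense-layer
#' kernels of the classification head.
#'
#' @param learningRate Initial Adam learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param batchSize Mini-batch size.
#' @param maxEpochs Epoch budget.
#' @param plateauFactor Multiplier applied to the learning rate on a plateau.
#' @param plateauPatience Consecutive non-improving epochs before reducing.
#' @param minLr Learning-rate floor.
#' @param earlyStopPatience Consecutive non-improving epochs before stopping.
#' @param l2Lambda l2 penalty coefficient.
#' @param l2Scope \code{"head"} penalizes the hidden dense kernels only;
#'   \code{"all"} penalizes every trainable weight (global decay).
#' @param seed Integer seed controlling shuffling, augmentation and dropout.
#' @return A validated list of class \code{"TrainingConfig"}.
#' @export
trainingConfig <- function(learningRate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                           batchSize = 32L, maxEpochs = 50L,
                           plateauFactor = 0.5, plateauPatience = 5L,
                           minLr = 1e-6, earlyStopPatience = 15L,
                           l2Lambda = 0.01, l2Scope = "head", seed = 1L) {
  stopifnot(learningRate > 0, plateauFactor > 0, plateauFactor < 1,
            minLr <= learningRate, plateauPatience >= 1L,
            earlyStopPatience >= 1L, batchSize >= 1L, maxEpochs >= 1L,
            l2Lambda >= 0, l2Scope %in% c("head", "all"))
  structure(list(learningRate = learningRate, beta1 = beta1, beta2 = beta2,
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 plateauFactor = plateauFactor,
                 plateauPatience = as.integer(plateauPatience), minLr = minLr,
                 earlyStopPatience = as.integer(earlyStopPatience),
                 l2Lambda = l2Lambda, l2Scope = l2Scope,
                 seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' Regularized cross-entropy loss
#'
#' Mean negative log-probability of the true classes over the batch plus
#' \code{lambda} times the sum of squared penalized weights. Probabilities at
#' a true label that underflow to zero are clamped at 1e-12 with a warning.
#'
#' @param probabilities B x N matrix; strictly positive rows summing to 1.
#' @param trueLabels Integer vector of 0-based class indices, length B.
#' @param penalizedWeights Numeric vector/array (or list of them) entering
#'   the l2 penalty; may be empty.
#' @param lambda Penalty coefficient.
#' @return Scalar loss.
#' @examples
#' p <- matrix(1 / 10, 4, 10)
#' regularizedLoss(p, c(0L, 3L, 9L, 5L), numeric(0), 0.01) # log(10)
#' @export
regularizedLoss <- function(probabilities, trueLabels, penalizedWeights = list(),
                            lambda = 0.01) {
  b <- nrow(probabilities)
  stopifnot(length(trueLabels) == b)
  py <- probabilities[cbind(seq_len(b), as.integer(trueLabels) + 1L)]
  if (any(py < 1e-12)) {
    warning("true-class probability clamped at 1e-12", call. = FALSE)
    py <- pmax(py, 1e-12)
  }
  if (!is.list(penalizedWeights)) penalizedWeights <- list(penalizedWeights)
  pen <- sum(vapply(penalizedWeights, function(w) sum(w^2), numeric(1)), 0)
  -mean(log(py)) + lambda * pen
}

# walk a monitored loss sequence with the (patience, reset-on-trigger)
# plateau/early-stop state machine; returns per-epoch wait counters and the
# running best
monitorWalk <- function(losses, patience, onTrigger = NULL) {
  best <- Inf; wait <- 0L
  out <- numeric(length(losses))
  trig <- logical(length(losses))
  for (e in seq_along(losses)) {
    if (losses[e] < best) { best <- losses[e]; wait <- 0L }
    else wait <- wait + 1L
    if (wait >= patience) { trig[e] <- TRUE; wait <- 0L }
    out[e] <- wait
  }
  list(wait = out, triggered = trig)
}

#' Next learning rate under reduce-on-plateau
#'
#' Replays the validation-loss history through the schedule: whenever the
#' monitored loss fails to improve on its running best for
#' \code{plateauPatience} consecutive epochs, the learning rate is multiplied
#' by \code{plateauFactor} (never below \code{minLr}) and the stagnation
#' counter resets.
#'
#' @param history A \linkS4class{TrainingHistory} or a numeric vector of
#'   validation losses.
#' @param config A \code{\link{trainingConfig}}.
#' @return The learning rate in force after the last recorded epoch.
#' @export
nextPlateauLr <- function(history, config = trainingConfig()) {
  losses <- if (is(history, "TrainingHistory")) history@records$val_loss
            else as.numeric(history)
  stopifnot(length(losses) >= 1L)
  w <- monitorWalk(losses, config$plateauPatience)
  lr <- config$learningRate
  for (e in seq_along(losses))
    if (w$triggered[e]) lr <- max(lr * config$plateauFactor, config$minLr)
  lr
}

#' Early-stopping decision
#'
#' Stops when the monitored validation loss has not improved for
#' \code{earlyStopPatience} consecutive epochs; the restore epoch is the
#' (first) epoch with the minimum validation loss.
#'
#' @inheritParams nextPlateauLr
#' @return List with \code{stop} (logical) and \code{restoreEpoch} (1-based).
#' @export
earlyStop <- function(history, config = trainingConfig()) {
  losses <- if (is(history, "TrainingHistory")) history@records$val_loss
            else as.numeric(history)
  stopifnot(length(losses) >= 1L)
  w <- monitorWalk(losses, config$earlyStopPatience)
  list(stop = any(w$triggered), restoreEpoch = which.min(losses))
}

penalizedParamNames <- function(model, scope) {
  if (scope == "all") {
    out <- list()
    for (ln in names(model@layers))
      for (pn in names(model@layers[[ln]]$params))
        out[[length(out) + 1L]] <- c(ln, pn)
    return(out)
  }
  # head scope: kernels of the hidden dense layers only
  hid <- grep("^fc[0-9]+$", names(model@layers), value = TRUE)
  lapply(hid, function(ln) c(ln, "W"))
}

l2Penalty <- function(model, pens, lambda) {
  lambda * sum(vapply(pens, function(pp)
    sum(model@layers[[pp[1]]]$params[[pp[2]]]^2), numeric(1)), 0)
}

ceLossAcc <- function(probs, yTrue) {
  py <- pmax(probs[cbind(seq_len(nrow(probs)), yTrue + 1L)], 1e-12)
  pred <- max.col(probs, ties.method = "first") - 1L
  c(loss = -mean(log(py)), acc = mean(pred == yTrue))
}

# inference pass in batches; returns B x N probability matrix
predictInBatches <- function(model, imgs, idx, batchSize = 64L) {
  out <- matrix(0, length(idx), model@spec@numClasses)
  for (s in split(seq_along(idx), ceiling(seq_along(idx) / batchSize))) {
    out[s, ] <- modelForward(model, imgs[, , , idx[s], drop = FALSE],
                             training = FALSE)$probs
  }
  out
}

#' Train the model
#'
#' Mini-batch Adam training with per-epoch augmented training streams, a
#' validation pass each epoch and callbacks applied in order: checkpoint
#' (tracks the best validation accuracy and keeps those weights), plateau
#' learning-rate reduction and early stopping (both monitoring validation
#' loss). The returned model carries the best checkpoint's weights. Training
#' aborts with a diagnostic if the loss diverges to NaN.
#'
#' @param model A built \linkS4class{FundusModel}.
#' @param dataset A \linkS4class{FundusDataset}.
#' @param split A \code{\link{stratifiedSplit}} result.
#' @param config A \code{\link{trainingConfig}}.
#' @param augment An \code{\link{augmentationConfig}} for the training
#'   stream, or NULL to disable augmentation.
#' @param verbose Print a line per epoch.
#' @return List with \code{model} (best weights) and \code{history}
#'   (\linkS4class{TrainingHistory}).
#' @export
trainModel <- function(model, dataset, split, config = trainingConfig(),
                       augment = augmentationConfig(), verbose = FALSE) {
  set.seed(config$seed)
  imgs <- dataset@images
  labs <- dataset@labels
  nClass <- model@spec@numClasses
  pens <- penalizedParamNames(model, config$l2Scope)
  lam <- config$l2Lambda
  adam <- list()  # per "layer/param" moment arrays
  tStep <- 0L
  lr <- config$learningRate
  bestMonitor <- -Inf
  bestLayers <- model@layers
  bestEp <- 1L
  plateauBest <- Inf; plateauWait <- 0L
  stopBest <- Inf; stopWait <- 0L
  rec <- data.frame()
  for (ep in seq_len(config$maxEpochs)) {
    ord <- sample(split$train)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    epLoss <- 0; epAcc <- 0; epN <- 0
    for (bi in batches) {
      xb <- imgs[, , , bi, drop = FALSE]
      if (!is.null(augment)) xb <- augmentBatch(xb, augment)
      yb <- labs[bi]
      fw <- modelForward(model, xb, training = TRUE, keepCache = TRUE)
      model <- fw$model
      p <- t(fw$probs)  # N x B
      la <- ceLossAcc(fw$probs, yb)
      loss <- la["loss"] + l2Penalty(model, pens, lam)
      if (!is.finite(loss))
        stop("divergent loss (NaN/Inf) at epoch ", ep,
             "; reduce the learning rate")
      onehot <- matrix(0, nClass, length(yb))
      onehot[cbind(yb + 1L, seq_along(yb))] <- 1
      bw <- modelBackward(model, fw$caches, (p - onehot) / length(yb),
                          training = TRUE)
      grads <- bw$grads
      for (pp in pens) {
        g <- grads[[pp[1]]][[pp[2]]]
        if (is.null(g)) g <- 0
        grads[[pp[1]]][[pp[2]]] <-
          g + 2 * lam * model@layers[[pp[1]]]$params[[pp[2]]]
      }
      tStep <- tStep + 1L
      corr1 <- 1 - config$beta1^tStep
      corr2 <- 1 - config$beta2^tStep
      for (ln in names(grads)) {
        for (pn in names(grads[[ln]])) {
          key <- paste0(ln, "/", pn)
          g <- grads[[ln]][[pn]]
          if (is.null(adam[[key]]))
            adam[[key]] <- list(m = g * 0, v = g * 0)
          adam[[key]]$m <- config$beta1 * adam[[key]]$m + (1 - config$beta1) * g
          adam[[key]]$v <- config$beta2 * adam[[key]]$v + (1 - config$beta2) * g^2
          upd <- lr * (adam[[key]]$m / corr1) /
            (sqrt(adam[[key]]$v / corr2) + 1e-8)
          model@layers[[ln]]$params[[pn]] <-
            model@layers[[ln]]$params[[pn]] - upd
        }
      }
      epLoss <- epLoss + loss * length(yb)
      epAcc <- epAcc + la["acc"] * length(yb)
      epN <- epN + length(yb)
    }
    valProbs <- predictInBatches(model, imgs, split$val)
    vla <- ceLossAcc(valProbs, labs[split$val])
    valLoss <- vla["loss"] + l2Penalty(model, pens, lam)
    rec <- rbind(rec, data.frame(
      epoch = ep, lr = lr, train_loss = epLoss / epN, train_acc = epAcc / epN,
      val_loss = valLoss, val_acc = vla["acc"]))
    if (verbose)
      message(sprintf(
        "epoch %02d lr %.2e train %.4f/%.3f val %.4f/%.3f", ep, lr,
        epLoss / epN, epAcc / epN, valLoss, vla["acc"]))
    # callbacks: checkpoint -> plateau -> early stop
    if (vla["acc"] > bestMonitor) {
      bestMonitor <- vla["acc"]
      bestLayers <- model@layers
      bestEp <- ep
    }
    if (valLoss < plateauBest) { plateauBest <- valLoss; plateauWait <- 0L }
    else plateauWait <- plateauWait + 1L
    if (plateauWait >= config$plateauPatience) {
      lr <- max(lr * config$plateauFactor, config$minLr)
      plateauWait <- 0L
    }
    if (valLoss < stopBest) { stopBest <- valLoss; stopWait <- 0L }
    else stopWait <- stopWait + 1L
    if (stopWait >= config$earlyStopPatience) break
  }
  model@layers <- bestLayers
  rownames(rec) <- NULL
  list(model = model,
       history = new("TrainingHistory", records = rec,
                     bestEpoch = bestEp, stoppedEpoch = as.integer(nrow(rec))))
}
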
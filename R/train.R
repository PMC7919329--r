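#' Training configuration
#'
#' Hyperparameters of the training loop. Defaults follow the reference
#' protocol for this architecture: batch size 8, 250 epochs, validation
#' split 0.30, Adam with learning rate 0.0001, weighted dice loss for the
#' liver and tumor-from-liver tasks and binary cross-entropy for
#' tumor-from-abdomen.
#'
#' @param batchSize slices per optimization step
#' @param epochs full passes over the training set
#' @param validationSplit fraction held out for validation, in (0, 1)
#' @param learningRate Adam learning rate
#' @param optimizer only \code{"adam"} is implemented
#' @param loss \code{"weighted_dice"} or \code{"bce"}
#' @param lossWeight weight factor W of the dice loss: a positive number,
#'   or \code{"inverse-ratio"} to estimate it from the pooled training
#'   masks (\code{\link{estimateWeight}})
#' @param threshold probability threshold for binary predictions
#' @param seed integer seed controlling split, shuffling, dropout and
#'   augmentation
#' @param checkpointPath optional path; the best-validation-DSC parameter
#'   snapshot is saved there as an RDS file
#' @return a validated configuration (classed list)
#' @export
trainConfig <- function(batchSize = 8L, epochs = 250L,
                        validationSplit = 0.30, learningRate = 1e-4,
                        optimizer = "adam",
                        loss = c("weighted_dice", "bce"),
                        lossWeight = 1, threshold = 0.5, seed = 1L,
                        checkpointPath = NULL) {
  loss <- match.arg(loss)
  optimizer <- match.arg(optimizer, "adam")
  stopifnot(batchSize >= 1, epochs >= 0,
            validationSplit > 0, validationSplit < 1, learningRate > 0,
            threshold >= 0, threshold <= 1)
  if (is.numeric(lossWeight) && lossWeight <= 0)
    stop("lossWeight must be positive")
  structure(list(batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 validationSplit = validationSplit,
                 learningRate = learningRate, optimizer = optimizer,
                 loss = loss, lossWeight = lossWeight,
                 threshold = threshold, seed = as.integer(seed),
                 checkpointPath = checkpointPath),
            class = "trainConfig")
}

#' Assemble inputs, targets and default loss for one experiment
#'
#' The three segmentation experiments supported by this pipeline:
#' \describe{
#'   \item{liver}{abdomen image -> liver mask, weighted dice loss}
#'   \item{tumor_from_liver}{liver-masked image (abdomen image with
#'     pixels outside the liver zeroed) -> tumor mask, weighted dice loss}
#'   \item{tumor_from_abdomen}{abdomen image -> tumor mask, binary
#'     cross-entropy}
#' }
#'
#' @param volume a \linkS4class{VolumePair}
#' @param experiment experiment tag (see Description)
#' @return list with \code{images} (H, W, n), \code{masks} (H, W, n),
#'   \code{loss} (default loss name) and \code{target} ("liver" or
#'   "tumor", the mask the slice filter should test)
#' @export
makeExperiment <- function(volume,
                           experiment = c("liver", "tumor_from_liver",
                                          "tumor_from_abdomen")) {
  stopifnot(is(volume, "VolumePair"))
  experiment <- match.arg(experiment)
  switch(experiment,
    liver = list(images = volume@images, masks = volume@liverMasks,
                 loss = "weighted_dice", target = "liver"),
    tumor_from_liver = list(images = volume@images * volume@liverMasks,
                            masks = volume@tumorMasks,
                            loss = "weighted_dice", target = "tumor"),
    tumor_from_abdomen = list(images = volume@images,
                              masks = volume@tumorMasks,
                              loss = "bce", target = "tumor"))
}

#' Random train/validation split
#'
#' Disjoint, exhaustive per-slice split with \code{round(fraction * n)}
#' validation slices, reproducible by seed.
#'
#' @param n number of slices
#' @param fraction validation fraction in (0, 1)
#' @param seed integer seed
#' @return list with integer index vectors \code{train} and \code{val}
#' @export
splitTrainVal <- function(n, fraction = 0.30, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  if (n < 2) stop("need at least 2 slices to split")
  nVal <- max(1L, round(fraction * n))
  if (nVal >= n) nVal <- n - 1L
  set.seed(seed)
  val <- sort(sample.int(n, nVal))
  list(train = setdiff(seq_len(n), val), val = val)
}

asBatch <- function(images, idx) {
  d <- dim(images)
  array(images[, , idx], c(d[1], d[2], 1L, length(idx)))
}

batchLossGrad <- function(prob, target, lossName, W, threshold) {
  nb <- dim(prob)[4L]
  loss <- 0
  if (lossName == "weighted_dice") {
    dLdp <- array(0, dim(prob))
    for (s in seq_len(nb)) {
      p <- prob[, , 1L, s]
      y <- target[, , 1L, s]
      loss <- loss + weightedDiceLoss(p, y, W = W)
      dLdp[, , 1L, s] <- weightedDiceLossGrad(p, y, W = W)
    }
    loss <- loss / nb
    dlogits <- dLdp * prob * (1 - prob) / nb
  } else {
    loss <- binaryCrossEntropy(prob, target)
    np <- dim(prob)[1L] * dim(prob)[2L]
    dlogits <- (prob - target) / (np * nb)
  }
  list(loss = loss, dlogits = dlogits)
}

adamInit <- function(params) {
  zeros <- lapply(params, function(p) lapply(p, function(a) {
    z <- a; z[] <- 0; z
  }))
  list(m = zeros, v = zeros, t = 0L)
}

adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    # align gradient component names to parameter component names
    comp <- names(params[[nm]])
    gv <- if (!is.null(g$w)) list(g$w, g$b) else list(g$gamma, g$beta)
    for (j in seq_along(comp)) {
      opt$m[[nm]][[j]] <- beta1 * opt$m[[nm]][[j]] + (1 - beta1) * gv[[j]]
      opt$v[[nm]][[j]] <- beta2 * opt$v[[nm]][[j]] +
        (1 - beta2) * gv[[j]]^2
      params[[nm]][[j]] <- params[[nm]][[j]] -
        lr * (opt$m[[nm]][[j]] / c1) /
          (sqrt(opt$v[[nm]][[j]] / c2) + eps)
    }
  }
  list(params = params, opt = opt)
}

evaluateModel <- function(model, images, masks, threshold,
                          lossName = NULL, W = 1, batchSize = 8L) {
  n <- dim(images)[3L]
  dscSum <- 0
  lossSum <- 0
  nBatches <- 0L
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    x <- asBatch(images, idx)
    y <- asBatch(masks, idx)
    prob <- unetForward(model, x, training = FALSE, keepCache = FALSE)$prob
    for (s in seq_along(idx)) {
      cc <- confusionCounts((prob[, , 1L, s] >= threshold) * 1,
                            y[, , 1L, s])
      dscSum <- dscSum + dsc(cc)
    }
    if (!is.null(lossName)) {
      lossSum <- lossSum + batchLossGrad(prob, y, lossName, W,
                                         threshold)$loss
      nBatches <- nBatches + 1L
    }
  }
  list(dsc = dscSum / n,
       loss = if (!is.null(lossName)) lossSum / nBatches else NA_real_)
}

#' Train a U-Net
#'
#' Runs the Adam-optimized training loop with optional on-the-fly affine
#' augmentation (a fresh transform per slice per epoch). Per epoch the
#' history records the mean optimized batch loss and the mean DSC of the
#' thresholded training-batch predictions (both with dropout active, as
#' optimized), plus the validation loss/DSC evaluated in inference mode.
#' Use \code{\link{predictMask}} for an inference-mode training-set
#' score. The parameter snapshot
#' with the best validation DSC is kept (and written to
#' \code{checkpointPath} if configured) and the history marks the best
#' epoch; the model retains its final-epoch weights.
#'
#' Model state is updated in place (the model object's state environment),
#' so the returned list's \code{model} is the same object as the argument.
#'
#' @param model a \linkS4class{UNetModel}
#' @param images training images, array (H, W, n) in [0, 1]
#' @param masks aligned binary target masks (H, W, n)
#' @param config a \code{\link{trainConfig}}
#' @param augmentation optional \code{\link{augmentationConfig}} for
#'   on-the-fly augmentation; NULL disables it
#' @param valImages,valMasks optional validation arrays; when NULL,
#'   validation metrics are NA and checkpointing tracks training DSC
#' @param verbose print one line per epoch
#' @return list with \code{model}, \code{history} (data.frame with one row
#'   per epoch: epoch, trainLoss, trainDsc, valLoss, valDsc),
#'   \code{bestEpoch} and \code{bestParams}
#' @export
trainModel <- function(model, images, masks, config,
                       augmentation = NULL, valImages = NULL,
                       valMasks = NULL, verbose = FALSE) {
  stopifnot(is(model, "UNetModel"), inherits(config, "trainConfig"))
  n <- dim(images)[3L]
  if (config$batchSize > n)
    stop("batchSize (", config$batchSize,
         ") exceeds the training-set size (", n, ")")
  W <- if (identical(config$lossWeight, "inverse-ratio"))
    estimateWeight(masks, "inverse-ratio") else config$lossWeight
  if (!is.null(augmentation) && isIdentityAugmentation(augmentation))
    augmentation <- NULL
  history <- data.frame(epoch = integer(), trainLoss = numeric(),
                        trainDsc = numeric(), valLoss = numeric(),
                        valDsc = numeric())
  if (config$epochs == 0L)
    return(list(model = model, history = history, bestEpoch = NA_integer_,
                bestParams = model@state$params))
  set.seed(config$seed)
  opt <- adamInit(model@state$params)
  bestScore <- -Inf
  bestEpoch <- NA_integer_
  bestParams <- model@state$params
  bestRunning <- model@state$running
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    epochLoss <- 0
    nBatches <- 0L
    dscSum <- 0
    for (start in seq(1L, n, by = config$batchSize)) {
      idx <- ord[start:min(start + config$batchSize - 1L, n)]
      if (is.null(augmentation)) {
        x <- asBatch(images, idx)
        y <- asBatch(masks, idx)
      } else {
        d <- dim(images)
        x <- array(0, c(d[1], d[2], 1L, length(idx)))
        y <- array(0, c(d[1], d[2], 1L, length(idx)))
        for (s in seq_along(idx)) {
          tr <- applyTransform(images[, , idx[s]], masks[, , idx[s]],
                               sampleTransform(augmentation),
                               fillMode = augmentation$fillMode)
          x[, , 1L, s] <- tr$image
          y[, , 1L, s] <- tr$mask
        }
      }
      fwd <- unetForward(model, x, training = TRUE)
      lg <- batchLossGrad(fwd$prob, y, config$loss, W, config$threshold)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", epoch,
             " (batch starting at slice ", start,
             "); try a lower learning rate")
      grads <- unetBackward(model, fwd$cache, lg$dlogits)
      upd <- adamStep(model@state$params, grads, opt, config$learningRate)
      model@state$params <- upd$params
      opt <- upd$opt
      for (s in seq_along(idx))
        dscSum <- dscSum + dsc(confusionCounts(
          (fwd$prob[, , 1L, s] >= config$threshold) * 1, y[, , 1L, s]))
      epochLoss <- epochLoss + lg$loss
      nBatches <- nBatches + 1L
    }
    trainDsc <- dscSum / n
    if (!is.null(valImages)) {
      valEval <- evaluateModel(model, valImages, valMasks,
                               config$threshold, config$loss, W,
                               config$batchSize)
      score <- valEval$dsc
    } else {
      valEval <- list(dsc = NA_real_, loss = NA_real_)
      score <- trainDsc
    }
    history <- rbind(history, data.frame(
      epoch = epoch, trainLoss = epochLoss / nBatches,
      trainDsc = trainDsc, valLoss = valEval$loss,
      valDsc = valEval$dsc))
    if (score > bestScore) {
      bestScore <- score
      bestEpoch <- epoch
      bestParams <- model@state$params
      bestRunning <- model@state$running
    }
    if (verbose)
      message(sprintf(
        "epoch %3d | loss %8.4f | train DSC %.4f | val loss %8.4f | val DSC %.4f",
        epoch, epochLoss / nBatches, trainDsc, valEval$loss,
        valEval$dsc))
  }
  if (!is.null(config$checkpointPath))
    saveRDS(list(config = model@config, params = bestParams,
                 running = bestRunning, epoch = bestEpoch),
            config$checkpointPath)
  list(model = model, history = history, bestEpoch = bestEpoch,
       bestParams = bestParams, bestRunning = bestRunning)
}

#' Predict binary masks
#'
#' Runs the model in inference mode (dropout off, running batch-norm
#' statistics) and thresholds the probability map.
#'
#' @param model a trained \linkS4class{UNetModel}
#' @param images matrix (H, W) or array (H, W, n), preprocessed the same
#'   way as the training data
#' @param threshold probability cut; pixels with probability >= threshold
#'   become foreground
#' @param batchSize slices per forward pass
#' @return binary mask(s) with the same spatial shape as the input
#' @export
predictMask <- function(model, images, threshold = 0.5, batchSize = 8L) {
  single <- is.matrix(images)
  if (single) images <- array(images, c(dim(images), 1L))
  d <- dim(images)
  if (d[1] %% model@config$poolSize^model@config$depth != 0 ||
      d[2] %% model@config$poolSize^model@config$depth != 0)
    stop("input spatial size ", d[1], " x ", d[2],
         " is not divisible by poolSize^depth; preprocess the slices ",
         "to a compatible size first")
  out <- array(0, d)
  for (start in seq(1L, d[3], by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, d[3])
    prob <- unetForward(model, asBatch(images, idx),
                        training = FALSE, keepCache = FALSE)$prob
    out[, , idx] <- (prob[, , 1L, ] >= threshold) * 1
  }
  if (single) out[, , 1L] else out
}

#' Run one segmentation experiment end to end
#'
#' Full pipeline on a phantom (or ingested) volume: experiment assembly
#' (\code{\link{makeExperiment}}), optional class-balancing slice
#' filtering, train/validation split, model construction, training with
#' augmentation, and evaluation of thresholded predictions on the
#' held-out slices.
#'
#' @param volume a \linkS4class{VolumePair}
#' @param experiment experiment tag, see \code{\link{makeExperiment}}
#' @param archConfig an \code{\link{architectureConfig}}; its
#'   \code{inputSize} must match the volume slices
#' @param config a \code{\link{trainConfig}}; its \code{loss} is
#'   overridden by the experiment default unless \code{keepLoss = TRUE}
#' @param augmentation optional \code{\link{augmentationConfig}}
#' @param filter apply the class-balancing slice filter before training
#' @param keepLoss keep \code{config$loss} instead of the experiment
#'   default
#' @param verbose print per-epoch progress
#' @return list with \code{model}, \code{history}, \code{metrics}
#'   (a \code{MetricsReport} on the held-out slices, best checkpoint
#'   weights), \code{balance} (ClassBalanceReport or NULL), \code{split}
#' @export
runExperiment <- function(volume, experiment, archConfig, config,
                          augmentation = augmentationConfig(),
                          filter = TRUE, keepLoss = FALSE,
                          verbose = FALSE) {
  exp <- makeExperiment(volume, experiment)
  if (!keepLoss) config$loss <- exp$loss
  images <- exp$images
  masks <- exp$masks
  balance <- NULL
  if (filter) {
    fl <- filterSlices(volume, exp$target)
    balance <- fl$report
    images <- images[, , fl$kept, drop = FALSE]
    masks <- masks[, , fl$kept, drop = FALSE]
  }
  n <- dim(images)[3L]
  split <- splitTrainVal(n, config$validationSplit, config$seed)
  model <- buildModel(archConfig)
  fit <- trainModel(model, images[, , split$train, drop = FALSE],
                    masks[, , split$train, drop = FALSE], config,
                    augmentation = augmentation,
                    valImages = images[, , split$val, drop = FALSE],
                    valMasks = masks[, , split$val, drop = FALSE],
                    verbose = verbose)
  # evaluate the best checkpoint on the held-out slices
  model@state$params <- fit$bestParams
  model@state$running <- fit$bestRunning
  pred <- predictMask(model, images[, , split$val, drop = FALSE],
                      config$threshold, config$batchSize)
  metrics <- evaluateMasks(pred, masks[, , split$val, drop = FALSE])
  list(model = model, history = fit$history, metrics = metrics,
       balance = balance, split = split, bestEpoch = fit$bestEpoch)
}
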
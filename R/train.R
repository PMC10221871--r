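## Training loop. The backbone is a fixed feature extractor; the trainable
## parameters are the shared 1x1 projection head. Because global average
## pooling commutes with the 1x1 projection, each branch's class scores are
## exactly (pooled standardized features) %*% W, so the composite loss has
## closed-form gradients through the softmax:
##   KL term:        dL/dscores = p - y
##   L1 term:        dL/dscores = p * (s - sum(p * s)),  s = sign(p - y)
##   temporal term:  dL/dscores = T(t) * (p - ybar)
## HOLM/APEM crops are hard attention: no gradient crosses a crop boundary.

.scoreGrad <- function(p, y, ybar = NULL, weight = 0) {
  g <- p - y
  s <- sign(p - y)
  g <- g + p * (s - sum(p * s))
  if (!is.null(ybar) && weight != 0 && sum(ybar) > 0)
    g <- g + weight * (p - ybar)
  g
}

# Standardization statistics for pooled backbone features, computed once
# from the training images' raw-branch features (a frozen normalization
# layer; keeps the head's gradient scale independent of the feature scale).
.fitFeatNorm <- function(feats) {
  d <- dim(feats[[1]])
  pooled <- t(vapply(feats, function(F_)
    colMeans(matrix(F_, nrow = d[1] * d[2])), numeric(d[3])))
  mean <- colMeans(pooled)
  sd <- apply(pooled, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-6] <- 1
  list(mean = mean, sd = sd)
}

.loadTrainingImages <- function(manifest) {
  lapply(manifest$image_path, readImageGray)
}

#' Train the three-branch bone-age model
#'
#' Per epoch: encode report labels as Gaussian distributions at the
#' configured sigma, run all three branches per image, compute the composite
#' loss (KL + L1 per branch, plus the ramped temporal term for the raw and
#' hand branches), take momentum-SGD steps on the projection head per
#' mini-batch, then advance the per-branch prediction ensembles. Rows whose
#' labels neither parse nor carry `mu_months` are skipped and counted; if
#' all rows are skipped training aborts. When a validation manifest is given
#' the head that achieves the best validation MAE is kept for prediction.
#' All randomness (head init, batch order) flows from `config$seed`, so two
#' runs with the same inputs are identical; `resume` continues a run
#' bit-identically from its stored RNG state.
#'
#' @param manifest Training manifest: data frame or CSV path with
#'   `image_path, label_text` (optional `mu_months, split`).
#' @param config A [baaConfig()] / [deskConfig()].
#' @param valManifest Optional validation manifest for model selection.
#' @param resume A [BoneAgeModel-class] to continue training (its config is
#'   reused; `epochs` in `config` is the new total).
#' @param lossLogPath Optional CSV path; the per-epoch loss log is written
#'   there after every epoch.
#' @param verbose Print one line per epoch.
#' @return A [BoneAgeModel-class].
#' @export
trainBoneAge <- function(manifest, config = deskConfig(),
                         valManifest = NULL, resume = NULL,
                         lossLogPath = NULL, verbose = FALSE) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  if (is.character(valManifest)) valManifest <- readManifest(valManifest)
  if (!is.null(resume)) config <- resume@config

  Y <- encodeLabels(manifest, sigma = config$sigma)
  ok <- !is.na(attr(Y, "mu"))
  nSkipped <- sum(!ok)
  if (nSkipped > 0)
    warning(sprintf("%d manifest rows had unparseable labels and were skipped",
                    nSkipped))
  if (!any(ok)) stop("no usable labels in the manifest")
  manifest <- manifest[ok, , drop = FALSE]
  Y <- Y[ok, , drop = FALSE]
  n <- nrow(manifest)

  # letterbox once: every downstream consumer works in the input frame
  images <- lapply(.loadTrainingImages(manifest), letterboxResize,
                   size = config$inputSize)

  if (is.null(resume)) {
    backbone <- tinyBackbone(seed = config$seed)
    K <- attr(backbone, "K")
    rs <- .saveRNG()
    set.seed(config$seed)
    W <- matrix(stats::rnorm(K * boneAgeBins(), sd = 0.01),
                K, boneAgeBins())
    # frozen standardization from the training images' raw features
    rawFeats <- lapply(images, backboneForward, backbone = backbone)
    featNorm <- .fitFeatNorm(rawFeats)
    model <- new("BoneAgeModel",
                 backbone = backbone, projection = W, featNorm = featNorm,
                 config = unclass(config),
                 states = list(raw = ensembleState(n, config$gamma),
                               hand = ensembleState(n, config$gamma)),
                 trainState = list(projection = W,
                                   velocity = W * 0,
                                   rng = NULL,
                                   best = list(mae = Inf, projection = W,
                                               epoch = 0L)),
                 epoch = 0L, seed = config$seed,
                 lossLog = data.frame())
    startEpoch <- 1L
  } else {
    model <- resume
    rs <- .saveRNG()
    .restoreRNG(model@trainState$rng)
    startEpoch <- model@epoch + 1L
    if (startEpoch > config$epochs)
      stop("resume: config$epochs must exceed the completed epoch count")
  }
  # cache Branch-1 features once: the raw image never changes across epochs
  rawFeats <- lapply(images, backboneForward, backbone = model@backbone)

  schedule <- rampSchedule(tMax = config$tMax,
                           rampLength = config$rampLength)
  W <- model@trainState$projection
  V <- model@trainState$velocity
  states <- model@states
  best <- model@trainState$best
  lossLog <- model@lossLog

  valImages <- NULL
  valTruth <- NULL
  if (!is.null(valManifest)) {
    valY <- encodeLabels(valManifest, sigma = config$sigma)
    vok <- !is.na(attr(valY, "mu"))
    valManifest <- valManifest[vok, , drop = FALSE]
    valTruth <- attr(valY, "mu")[vok]
    valImages <- lapply(.loadTrainingImages(valManifest), letterboxResize,
                        size = config$inputSize)
  }

  for (epoch in startEpoch:config$epochs) {
    lr <- config$learningRate *
      0.1^((epoch - 1) %/% config$lrDecayEvery)
    weight <- rampWeight(epoch - 1L, schedule)
    ybarRaw <- if (states$raw@epoch > 0)
      states$raw@assembled / (1 - config$gamma^states$raw@epoch) else NULL
    ybarHand <- if (states$hand@epoch > 0)
      states$hand@assembled / (1 - config$gamma^states$hand@epoch) else NULL

    order <- sample.int(n)
    predRaw <- matrix(0, n, boneAgeBins())
    predHand <- matrix(0, n, boneAgeBins())
    comp <- c(raw = 0, hand = 0, parts = 0)

    batches <- split(order, ceiling(seq_along(order) / config$batchSize))
    for (batch in batches) {
      grad <- W * 0
      modelCur <- model
      modelCur@projection <- W
      for (i in batch) {
        rawHead <- .headFromFeatures(rawFeats[[i]], modelCur)
        fwd <- forwardMultibranch(images[[i]], modelCur, rawHead = rawHead)
        y <- Y[i, ]
        ybR <- if (!is.null(ybarRaw)) ybarRaw[i, ] else NULL
        ybH <- if (!is.null(ybarHand)) ybarHand[i, ] else NULL
        grad <- grad +
          outer(fwd$fbars$raw, .scoreGrad(fwd$raw, y, ybR, weight)) +
          outer(fwd$fbars$hand, .scoreGrad(fwd$hand, y, ybH, weight))
        if (length(fwd$parts)) {
          for (k in seq_along(fwd$parts)) {
            grad <- grad + outer(fwd$fbars$parts[[k]],
                                 .scoreGrad(fwd$parts[[k]], y)) /
              length(fwd$parts)
          }
        }
        predRaw[i, ] <- fwd$raw
        predHand[i, ] <- fwd$hand
        tl <- totalLoss(fwd, y,
                        ybarRaw = if (!is.null(ybR)) matrix(ybR, 1) else NULL,
                        ybarHand = if (!is.null(ybH)) matrix(ybH, 1) else NULL,
                        weight = weight)
        comp <- comp + attr(tl, "components")
      }
      grad <- grad / length(batch)
      V <- config$momentum * V + grad
      W <- W - lr * V
    }

    comp <- comp / n
    total <- sum(comp)

    # advance the per-branch prediction ensembles
    states$raw <- emaUpdate(states$raw, predRaw)$state
    states$hand <- emaUpdate(states$hand, predHand)$state

    valMae <- NA_real_
    if (!is.null(valImages) && length(valImages)) {
      modelCur <- model
      modelCur@projection <- W
      preds <- vapply(valImages, function(im)
        predictAge(im, modelCur), numeric(1))
      valMae <- mean(abs(preds - valTruth))
      if (valMae < best$mae)
        best <- list(mae = valMae, projection = W, epoch = epoch)
    }

    lossLog <- rbind(lossLog, data.frame(
      epoch = epoch, L_raw = comp[["raw"]], L_hand = comp[["hand"]],
      L_parts = comp[["parts"]], T_t = weight, L_total = total,
      val_mae = valMae))
    if (!is.null(lossLogPath))
      utils::write.csv(lossLog, lossLogPath, row.names = FALSE)
    if (verbose)
      message(sprintf(
        "epoch %3d  loss %.4f (raw %.4f hand %.4f parts %.4f)  T %.4f%s",
        epoch, total, comp[["raw"]], comp[["hand"]], comp[["parts"]], weight,
        if (is.finite(valMae)) sprintf("  val MAE %.2f", valMae) else ""))
  }

  model@projection <- if (is.finite(best$mae)) best$projection else W
  model@trainState <- list(projection = W, velocity = V,
                           rng = .saveRNG(), best = best)
  model@states <- states
  model@epoch <- as.integer(config$epochs)
  model@lossLog <- lossLog
  .restoreRNG(rs)
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file containing weights, configuration,
#' ensemble states, epoch counter, seed and RNG state.
#'
#' @param model A [BoneAgeModel-class].
#' @param path Checkpoint file.
#' @return `path` (save) or the model (load).
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
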
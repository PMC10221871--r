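## Three-branch pipeline: raw image branch, hand-crop branch (via HOLM) and
## bone-part branch (via APEM) share one backbone and one 1x1 projection
## head. Training follows momentum SGD on the composite distribution loss
## with per-branch temporal ensembling; at test time the hand branch is the
## prediction output.

#' Training configuration
#'
#' Defaults follow the full-scale recipe (576-pixel inputs, batch size 32,
#' momentum SGD at 0.001 decayed x0.1 every 30 epochs, sigma = 3 months,
#' tau = 0.6) with the pipeline-specific settings (eta, part count, NMS
#' threshold, anchor stride, gamma, tMax) documented where they are used.
#' `deskConfig()` is the small preset used throughout the examples and
#' tests.
#'
#' @param sigma Label-distribution spread in months.
#' @param tau HOLM mask threshold in (0, 1).
#' @param eta APEM stretch factor.
#' @param nParts Bone parts per image.
#' @param iouThreshold NMS suppression threshold.
#' @param gamma Temporal-ensembling momentum in (0, 1).
#' @param tMax Maximum temporal-loss weight.
#' @param rampLength Epochs to ramp the temporal weight to `tMax`; `NULL`
#'   (default) resolves to 80% of `epochs`.
#' @param inputSize Branch-1/2 input side in pixels (divisible by 16).
#' @param partSize Part-crop side in pixels (divisible by 16).
#' @param anchorStride Anchor lattice stride on the 576-pixel frame.
#' @param batchSize Mini-batch size.
#' @param epochs Training epochs.
#' @param learningRate Initial SGD learning rate.
#' @param momentum SGD momentum.
#' @param lrDecayEvery Decay the learning rate x0.1 every this many epochs.
#' @param camRule `"argmax"` or `"soft"` channel choice for HOLM/APEM.
#' @param decode `"expectation"` or `"argmax"` readout for [decodeAge()].
#' @param seed Integer seed controlling all stochastic behaviour.
#' @return Validated configuration list of class `baa_config`.
#' @export
baaConfig <- function(sigma = 3, tau = 0.6, eta = 4, nParts = 4,
                      iouThreshold = 0.25, gamma = 0.6, tMax = 1,
                      rampLength = NULL, inputSize = 576L, partSize = 288L,
                      anchorStride = 32L, batchSize = 32L, epochs = 90L,
                      learningRate = 0.001, momentum = 0.9,
                      lrDecayEvery = 30L,
                      camRule = c("argmax", "soft"),
                      decode = c("expectation", "argmax"), seed = 1L) {
  camRule <- match.arg(camRule)
  decode <- match.arg(decode)
  if (is.null(rampLength)) rampLength <- max(1L, round(0.8 * epochs))
  cfg <- list(sigma = sigma, tau = tau, eta = eta, nParts = as.integer(nParts),
              iouThreshold = iouThreshold, gamma = gamma, tMax = tMax,
              rampLength = as.integer(rampLength),
              inputSize = as.integer(inputSize),
              partSize = as.integer(partSize),
              anchorStride = as.integer(anchorStride),
              batchSize = as.integer(batchSize), epochs = as.integer(epochs),
              learningRate = learningRate, momentum = momentum,
              lrDecayEvery = as.integer(lrDecayEvery), camRule = camRule,
              decode = decode, seed = as.integer(seed))
  stopifnot(cfg$sigma > 0, cfg$tau > 0, cfg$tau < 1, cfg$eta > 0,
            cfg$nParts >= 1, cfg$gamma > 0, cfg$gamma < 1, cfg$tMax > 0,
            cfg$inputSize %% 16L == 0L, cfg$partSize %% 16L == 0L,
            cfg$batchSize >= 1, cfg$epochs >= 1, cfg$learningRate > 0,
            cfg$momentum >= 0, cfg$momentum < 1)
  class(cfg) <- "baa_config"
  cfg
}

#' Desk-scale configuration preset
#'
#' 96-pixel inputs, 48-pixel part crops, 30 epochs, and a learning rate
#' suited to the shipped tiny backbone's linear projection head. All other
#' settings inherit the [baaConfig()] defaults.
#'
#' @param ... Overrides forwarded to [baaConfig()].
#' @return A `baa_config`.
#' @export
deskConfig <- function(...) {
  args <- list(...)
  defaults <- list(inputSize = 96L, partSize = 48L, epochs = 30L,
                   learningRate = 0.1, batchSize = 32L)
  defaults[names(args)] <- args
  do.call(baaConfig, defaults)
}

# Anchor configuration resolved for the configured input frame.
.resolveAnchors <- function(config) {
  scaleAnchorConfig(anchorConfig(stride = config$anchorStride),
                    frame = config$inputSize)
}

# One branch head: saturating standardized features -> activation map,
# pooled scores, softmax distribution, and the pooled feature vector the
# head's gradient factors through. The standardization is frozen (training
# set statistics) and saturates at 3 standard deviations so crop branches
# whose feature scale differs from raw images cannot blow up the shared
# head's gradients.
.branchHead <- function(image, model) {
  .headFromFeatures(backboneForward(image, model@backbone), model)
}

.headFromFeatures <- function(F_, model) {
  d <- dim(F_)
  z <- sweep(sweep(F_, 3, model@featNorm$mean, "-"), 3,
             model@featNorm$sd, "/")
  Fn <- 3 * tanh(z / 3)
  A <- projectFeatures(Fn, model@projection)
  p <- softmaxProbs(globalPool(A))
  list(A = A, p = p, fbar = colMeans(matrix(Fn, nrow = d[1] * d[2])),
       gridSize = d[1:2])
}

#' Forward pass of the three-branch network
#'
#' Branch 1 runs the backbone and projection head on the (letterboxed) raw
#' image; HOLM turns its activation into a hand crop; Branch 2 reruns the
#' head on the crop; APEM scores anchors on Branch 2's activation channel
#' and Branch 3 reruns the head on each of the top-N part crops.
#'
#' @param image Grayscale image matrix in \[0, 1\].
#' @param model A [BoneAgeModel-class].
#' @param rawHead Optional precomputed Branch-1 head output (feature cache).
#' @param partsToo Compute Branch 3 (default TRUE; prediction only needs
#'   Branch 2).
#' @return List: `raw`, `hand` (probability vectors), `parts` (list of
#'   probability vectors), `handBox` (in the letterboxed-image frame),
#'   `partRegions` (scored data frame), `fallback` (empty-mask flag), and
#'   the per-branch pooled features `fbars` used for gradient computation.
#' @export
forwardMultibranch <- function(image, model, rawHead = NULL,
                               partsToo = TRUE) {
  cfg <- model@config
  img1 <- letterboxResize(image, cfg$inputSize)
  if (is.null(rawHead)) rawHead <- .branchHead(img1, model)

  loc <- locateHand(rawHead$A, rawHead$p, imageSize = dim(img1),
                    tau = cfg$tau, cam = cfg$camRule)
  hand <- cropAndResize(img1, loc$box,
                        outSize = c(cfg$inputSize, cfg$inputSize))
  handHead <- .branchHead(hand, model)

  parts <- list()
  partFbars <- list()
  partRegions <- NULL
  if (partsToo) {
    c2 <- if (cfg$camRule == "argmax") selectChannel(handHead$p) else NULL
    channel <- if (is.null(c2)) {
      d <- dim(handHead$A)
      matrix(matrix(handHead$A, nrow = d[1] * d[2]) %*% handHead$p,
             d[1], d[2])
    } else handHead$A[, , c2]
    Abig <- resizeBilinear(channel, cfg$inputSize, cfg$inputSize)
    S <- stretchMap(Abig, cfg$eta)
    anchors <- generateAnchors(dim(S), .resolveAnchors(cfg))
    scored <- scoreRegions(S, anchors)
    kept <- topNParts(nmsRegions(scored, cfg$iouThreshold), cfg$nParts)
    partRegions <- kept
    crops <- extractParts(hand, kept,
                          partSize = c(cfg$partSize, cfg$partSize))
    heads <- lapply(crops, .branchHead, model = model)
    parts <- lapply(heads, `[[`, "p")
    partFbars <- lapply(heads, `[[`, "fbar")
  }

  list(raw = rawHead$p, hand = handHead$p, parts = parts,
       handBox = loc$box, partRegions = partRegions,
       fallback = loc$fallback,
       fbars = list(raw = rawHead$fbar, hand = handHead$fbar,
                    parts = partFbars))
}

#' Predict bone age for one image
#'
#' Applies the hand-branch rule: the raw branch only serves to localize the
#' hand; the decoded hand-branch distribution is the prediction. Branch 3 is
#' never consulted at test time.
#'
#' @param image Grayscale image matrix (or a file path).
#' @param model A trained [BoneAgeModel-class].
#' @param details Return the full distribution and hand box too?
#' @return Age in months, or (with `details = TRUE`) a list with `months`,
#'   `distribution`, `handBox`.
#' @export
predictAge <- function(image, model, details = FALSE) {
  if (is.character(image)) image <- readImageGray(image)
  out <- forwardMultibranch(image, model, partsToo = FALSE)
  months <- decodeAge(out$hand, method = model@config$decode)
  if (!details) return(months)
  list(months = months, distribution = out$hand, handBox = out$handBox)
}

#' Evaluate bone-age predictions
#'
#' Mean absolute error in months plus accuracy within each threshold
#' (a deviation exactly at the threshold counts as within, per the
#' plus-or-minus-k-months convention).
#'
#' @param predictions,truths Equal-length numeric vectors of months.
#' @param thresholds Accuracy windows in months. Default `c(6, 12, 24)`.
#' @return List of class `baa_eval`: `mae_months`, `acc` (named percentage
#'   vector), `n`.
#' @export
evaluateAges <- function(predictions, truths, thresholds = c(6, 12, 24)) {
  if (length(predictions) != length(truths) || length(truths) < 1L)
    stop("predictions and truths must be equal-length, non-empty")
  err <- abs(predictions - truths)
  acc <- vapply(thresholds, function(k) 100 * mean(err <= k), numeric(1))
  names(acc) <- paste0("acc", thresholds)
  structure(list(mae_months = mean(err), acc = acc, n = length(truths)),
            class = "baa_eval")
}

#' @export
print.baa_eval <- function(x, ...) {
  cat(sprintf("MAE: %.2f months (n = %d)\n", x$mae_months, x$n))
  for (nm in names(x$acc))
    cat(sprintf("  %s: %.2f%%\n", nm, x$acc[[nm]]))
  invisible(x)
}

#' Read a manifest CSV
#'
#' Expected columns: `image_path`, `label_text`, optional `mu_months`,
#' optional `split`. Paths are resolved relative to the manifest's own
#' directory when not found as given.
#'
#' @param path Manifest CSV with header.
#' @return Data frame.
#' @export
readManifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "label_text")
  if (!all(need %in% names(df)))
    stop("manifest must have columns image_path and label_text")
  miss <- !file.exists(df$image_path)
  if (any(miss)) {
    alt <- file.path(dirname(path), df$image_path[miss])
    df$image_path[miss][file.exists(alt)] <- alt[file.exists(alt)]
  }
  df
}

#' Encode a manifest's labels as distribution rows
#'
#' Parses each row's label text (falling back to `mu_months` when parsing
#' fails and the column is present), builds the Gaussian distribution, and
#' returns one row of 240 probabilities per image.
#'
#' @param manifest Data frame (or CSV path) with `label_text` and optionally
#'   `mu_months`.
#' @param sigma Distribution spread in months. Default 3.
#' @return Matrix (rows = images, 240 columns) with attribute `mu` (the
#'   per-row centres; NA where neither parse nor `mu_months` was available).
#' @export
encodeLabels <- function(manifest, sigma = 3) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  mus <- vapply(seq_len(nrow(manifest)), function(i) {
    mu <- tryCatch(labelToMu(parseReportLabel(manifest$label_text[i])),
                   baa_parse_error = function(e) NA_real_)
    if (is.na(mu) && "mu_months" %in% names(manifest))
      mu <- manifest$mu_months[i]
    mu
  }, numeric(1))
  Y <- matrix(NA_real_, nrow(manifest), boneAgeBins())
  ok <- !is.na(mus)
  for (i in which(ok)) Y[i, ] <- labelProbs(makeDistribution(mus[i], sigma))
  attr(Y, "mu") <- mus
  Y
}
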
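## Hand object location module (HOLM): a 1x1 convolutional projection of
## backbone features into per-class activation maps, global average pooling
## to class scores, softmax to a predicted label distribution, and a
## thresholded activation mask whose largest connected component yields the
## hand bounding box.

#' Project backbone features into per-class activation maps
#'
#' A pure per-pixel linear map (1x1 convolution, no bias):
#' \eqn{A_c(i,j) = \sum_k W_{kc} F(i,j,k)}.
#'
#' @param F_ Feature array of dimension H x W x K.
#' @param W Projection matrix of dimension K x C.
#' @return Activation array of dimension H x W x C.
#' @export
projectFeatures <- function(F_, W) {
  d <- dim(F_)
  if (length(d) != 3L) stop("features must be an H x W x K array")
  if (!is.matrix(W) || nrow(W) != d[3])
    stop(sprintf("projection must be a %d x C matrix", d[3]))
  A <- matrix(F_, nrow = d[1] * d[2], ncol = d[3]) %*% W
  array(A, dim = c(d[1], d[2], ncol(W)))
}

#' Global average pooling of an activation map
#'
#' @param A Activation array H x W x C.
#' @return Class-score vector of length C: per-channel spatial mean.
#' @export
globalPool <- function(A) {
  d <- dim(A)
  if (length(d) != 3L) stop("activation must be an H x W x C array")
  colMeans(matrix(A, nrow = d[1] * d[2], ncol = d[3]))
}

#' Softmax over class scores
#'
#' Computed with max-subtraction for overflow safety.
#'
#' @param scores Finite numeric vector.
#' @return Probability vector summing to 1.
#' @export
softmaxProbs <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Select the activation channel to localize with
#'
#' Returns the argmax class; ties break toward the lower index.
#'
#' @param p Probability vector summing to 1 within 1e-6.
#' @return Integer class index (1-based).
#' @export
selectChannel <- function(p) {
  if (abs(sum(p) - 1) > 1e-6) stop("p must sum to 1")
  which.max(p)
}

#' Threshold a normalized activation channel into a binary mask
#'
#' The channel is first min-max normalized to \[0, 1\]; the mask is 1 where
#' the normalized value is at least `tau`. A constant channel cannot be
#' normalized and yields an all-zero mask flagged as degenerate, with a
#' warning.
#'
#' @param channel Numeric matrix (one activation channel).
#' @param tau Threshold in (0, 1). Default 0.6.
#' @return Binary (0/1) matrix with attributes `tau` and `degenerate`.
#' @export
makeMask <- function(channel, tau = 0.6) {
  if (!(tau > 0 && tau < 1)) stop("tau must lie in (0, 1)")
  rng <- range(channel)
  degenerate <- rng[1] == rng[2]
  if (degenerate) {
    warning("constant activation channel: degenerate all-zero mask")
    m <- matrix(0, nrow(channel), ncol(channel))
  } else {
    m <- (minmaxNormalize(channel) >= tau) * 1
  }
  attr(m, "tau") <- tau
  attr(m, "degenerate") <- degenerate
  m
}

# 8-connected component labelling by breadth-first flood fill.
# Returns an integer matrix of component ids (0 = background).
labelComponents8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nextId <- 0L
  idx <- which(mask > 0)
  for (start in idx) {
    if (lab[start] != 0L) next
    nextId <- nextId + 1L
    queue <- start
    lab[start] <- nextId
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      r <- ((cur - 1L) %% H) + 1L
      cl <- ((cur - 1L) %/% H) + 1L
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0L && dx == 0L) next
        nr <- r + dy; nc <- cl + dx
        ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
        if (!any(ok)) next
        ni <- (nc[ok] - 1L) * H + nr[ok]
        ni <- ni[mask[ni] > 0 & lab[ni] == 0L]
        if (length(ni)) {
          lab[ni] <- nextId
          queue <- c(queue, ni)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Bounding box of the largest connected mask component
#'
#' Finds 8-connected components of positive mask pixels and returns the
#' tight bounding box of the largest one (ties break toward the component
#' encountered first in column-major scan order). An empty mask yields
#' `NULL` — the caller is expected to fall back to the full image.
#'
#' @param mask Binary (0/1) matrix, e.g. from [makeMask()].
#' @return A [roiBox()] in the mask's own (activation-grid) frame, or `NULL`
#'   if the mask has no positive pixel.
#' @export
maskToBox <- function(mask) {
  lab <- labelComponents8(mask)
  if (!any(lab > 0L)) return(NULL)
  sizes <- tabulate(lab)
  keep <- which.max(sizes)  # ties -> lowest id = first in scan order
  pos <- which(lab == keep, arr.ind = TRUE)
  roiBox(x0 = min(pos[, 2]) - 1L, y0 = min(pos[, 1]) - 1L,
         x1 = max(pos[, 2]), y1 = max(pos[, 1]))
}

#' Locate the hand from an activation map
#'
#' Convenience wrapper: picks the channel (argmax class by default, or the
#' probability-weighted channel sum when `cam = "soft"`), thresholds it, and
#' converts the largest mask component to a box rescaled to the source-image
#' frame.
#'
#' @param A Activation array H x W x C.
#' @param p Class probability vector (used for channel choice).
#' @param imageSize Source-image size `c(height, width)`.
#' @param tau Mask threshold in (0, 1). Default 0.6.
#' @param cam `"argmax"` (default) or `"soft"` (probability-weighted channel
#'   combination).
#' @return List with `box` (a [roiBox()] in image pixels, or the full-image
#'   box), and `fallback` (TRUE when the mask was empty/degenerate and the
#'   full image was used).
#' @export
locateHand <- function(A, p, imageSize, tau = 0.6, cam = c("argmax", "soft")) {
  cam <- match.arg(cam)
  d <- dim(A)
  channel <- if (cam == "argmax") {
    A[, , selectChannel(p)]
  } else {
    matrix(matrix(A, nrow = d[1] * d[2]) %*% p, d[1], d[2])
  }
  mask <- suppressWarnings(makeMask(channel, tau))
  box <- maskToBox(mask)
  if (is.null(box)) {
    return(list(box = roiBox(0, 0, imageSize[2], imageSize[1]),
                fallback = TRUE))
  }
  list(box = scaleBox(box, fromSize = d[1:2], toSize = imageSize),
       fallback = FALSE)
}
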
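## Distribution-learning objectives: forward KL and L1 terms between target
## and predicted label distributions, a temporal-ensembling consistency term
## with bias-corrected EMA targets, the ramp-up weight, and the per-branch /
## total losses.

.asProbMatrix <- function(x) {
  if (is(x, "LabelDistribution")) x <- x@probs
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x
}

.checkPair <- function(Y, Yhat) {
  Y <- .asProbMatrix(Y); Yhat <- .asProbMatrix(Yhat)
  if (!all(dim(Y) == dim(Yhat)))
    stop("target and prediction must have identical shapes")
  list(Y = Y, Yhat = Yhat)
}

#' Forward Kullback-Leibler loss between label distributions
#'
#' \eqn{L_{KL} = \frac{1}{m}\sum_i \sum_c y_{ic} \log(y_{ic}/\hat y_{ic})},
#' the standard non-negative forward KL averaged over the batch. Predicted
#' probabilities are clipped below at 1e-12; terms with \eqn{y_{ic} = 0}
#' contribute zero.
#'
#' @param Y Target distributions: vector, [LabelDistribution-class], or
#'   matrix (samples x bins).
#' @param Yhat Predicted distributions, same shape.
#' @return Non-negative scalar.
#' @export
klLoss <- function(Y, Yhat) {
  p <- .checkPair(Y, Yhat)
  q <- pmax(p$Yhat, 1e-12)
  terms <- ifelse(p$Y > 0, p$Y * log(p$Y / q), 0)
  sum(terms) / nrow(p$Y)
}

# Gradient of klLoss w.r.t. Yhat (before clipping): -Y / Yhat / m.
klLossGradYhat <- function(Y, Yhat) {
  p <- .checkPair(Y, Yhat)
  -p$Y / pmax(p$Yhat, 1e-12) / nrow(p$Y)
}

#' L1 loss between label distributions
#'
#' Batch mean of the elementwise L1 distance, summed over bins:
#' \eqn{\frac{1}{m}\sum_i \|y_i - \hat y_i\|_1}.
#'
#' @inheritParams klLoss
#' @return Non-negative scalar (at most 2 for probability vectors).
#' @export
maeLoss <- function(Y, Yhat) {
  p <- .checkPair(Y, Yhat)
  sum(abs(p$Y - p$Yhat)) / nrow(p$Y)
}

#' Temporal-ensembling consistency loss
#'
#' The same forward-KL kernel as [klLoss()] with the assembled (EMA)
#' predictions as target. Samples whose assembled target is still the zero
#' initialization (before their first EMA update) are excluded; the excluded
#' count is reported via the `nExcluded` attribute.
#'
#' @param Ybar Assembled target distributions (samples x bins).
#' @param Yhat Current predicted distributions, same shape.
#' @return Scalar loss (0 when every sample is excluded), with attribute
#'   `nExcluded`.
#' @export
temporalLoss <- function(Ybar, Yhat) {
  p <- .checkPair(Ybar, Yhat)
  live <- rowSums(p$Y) > 0
  nEx <- sum(!live)
  if (!any(live)) {
    out <- 0
  } else {
    out <- klLoss(p$Y[live, , drop = FALSE], p$Yhat[live, , drop = FALSE])
  }
  attr(out, "nExcluded") <- nEx
  out
}

#' Update the per-sample prediction ensemble
#'
#' One epoch step of temporal ensembling:
#' \eqn{S_t = \gamma S_{t-1} + (1-\gamma)\hat Y_t} followed by the
#' bias-corrected target \eqn{\bar Y_{t+1} = S_t / (1 - \gamma^t)}.
#'
#' @param state An [EnsembleState-class] at epoch \eqn{t-1}.
#' @param Yhat Predictions for every tracked sample (samples x bins), in the
#'   same row order as the state.
#' @return List with the advanced `state` and the new training `target`
#'   \eqn{\bar Y_{t+1}}.
#' @export
emaUpdate <- function(state, Yhat) {
  stopifnot(is(state, "EnsembleState"))
  Yhat <- .asProbMatrix(Yhat)
  if (!all(dim(Yhat) == dim(state@assembled)))
    stop("prediction matrix must match the tracked samples")
  t <- state@epoch + 1L
  S <- state@gamma * state@assembled + (1 - state@gamma) * Yhat
  target <- S / (1 - state@gamma^t)
  newState <- new("EnsembleState", assembled = S, gamma = state@gamma,
                  epoch = t)
  list(state = newState, target = target)
}

#' Ramp schedule for the temporal-ensembling weight
#'
#' @param tMax Maximum weight reached at the end of the ramp. Default 1.
#' @param rampLength Epochs over which normalized time goes 0 to 1.
#' @return List of class `baa_ramp`.
#' @export
rampSchedule <- function(tMax = 1, rampLength = 80L) {
  stopifnot(tMax > 0, rampLength >= 1)
  structure(list(tMax = tMax, rampLength = as.integer(rampLength)),
            class = "baa_ramp")
}

#' Time-dependent weight of the temporal-ensembling term
#'
#' \eqn{T(t) = T_{max} \exp(-5 (1 - t)^2)} with normalized time
#' \eqn{t = \min(\mathrm{epoch}/\mathrm{rampLength}, 1)}: near zero early in
#' training (when assembled predictions are unreliable), reaching
#' \eqn{T_{max}} at the end of the ramp.
#'
#' @param epoch Epoch counter, >= 0.
#' @param schedule A [rampSchedule()].
#' @return Weight in \eqn{(0, T_{max}]}, monotone non-decreasing in epoch.
#' @export
rampWeight <- function(epoch, schedule = rampSchedule()) {
  stopifnot(epoch >= 0)
  t <- min(epoch / schedule$rampLength, 1)
  schedule$tMax * exp(-5 * (1 - t)^2)
}

#' Loss of one branch
#'
#' KL + L1, plus `weight` times the temporal-consistency term for the raw
#' and hand branches (`useEnsembling = TRUE`). The bone-part branch omits the
#' temporal term because per-part predictions differ too much across epochs.
#'
#' @param Y Target distributions.
#' @param Yhat Branch predictions.
#' @param Ybar Assembled targets (ignored unless `useEnsembling`).
#' @param weight Ramp weight \eqn{T(t)} (ignored unless `useEnsembling`).
#' @param useEnsembling Include the temporal term?
#' @return Scalar loss.
#' @export
branchLoss <- function(Y, Yhat, Ybar = NULL, weight = 0,
                       useEnsembling = TRUE) {
  out <- klLoss(Y, Yhat) + maeLoss(Y, Yhat)
  if (useEnsembling && weight != 0) {
    if (is.null(Ybar)) stop("ensembling requested but no assembled target")
    out <- out + weight * as.numeric(temporalLoss(Ybar, Yhat))
  }
  out
}

#' Total three-branch loss
#'
#' \eqn{L_{total} = L_{raw} + L_{hand} + L_{boneParts}}: raw and hand
#' branches carry KL + L1 + ramped temporal terms; the part branch carries
#' KL + L1 averaged over the N part predictions.
#'
#' @param outputs List with elements `raw`, `hand` (probability vectors or
#'   matrices) and `parts` (list of probability vectors), as returned by
#'   [forwardMultibranch()].
#' @param Y Target distributions (same shape as `raw`).
#' @param ybarRaw,ybarHand Assembled targets for the two ensembled branches
#'   (or `NULL` to drop their temporal terms).
#' @param weight Ramp weight \eqn{T(t)}.
#' @return Scalar total loss with attribute `components`
#'   (`raw`, `hand`, `parts`).
#' @export
totalLoss <- function(outputs, Y, ybarRaw = NULL, ybarHand = NULL,
                      weight = 0) {
  lraw <- branchLoss(Y, outputs$raw, ybarRaw, weight,
                     useEnsembling = !is.null(ybarRaw))
  lhand <- branchLoss(Y, outputs$hand, ybarHand, weight,
                      useEnsembling = !is.null(ybarHand))
  lparts <- if (length(outputs$parts)) {
    mean(vapply(outputs$parts, function(p)
      branchLoss(Y, p, useEnsembling = FALSE), numeric(1)))
  } else 0
  total <- lraw + lhand + lparts
  attr(total, "components") <- c(raw = lraw, hand = lhand, parts = lparts)
  total
}
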
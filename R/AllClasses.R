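# Monthly label bins: skeletal age is quantized to an ordered set of 240
# one-month classes l_i = i, i = 1..240 (month 0 excluded: age is strictly
# positive).
.BONE_AGE_BINS <- 240L

#' Number of monthly bone-age bins
#'
#' The ordered label set used throughout the package: 240 one-month classes
#' \eqn{l_i = i} for \eqn{i = 1, \dots, 240} months. Month 0 is excluded
#' because bone age is strictly positive.
#'
#' @return Integer scalar, 240.
#' @export
boneAgeBins <- function() .BONE_AGE_BINS

#' Ambiguous bone-age label
#'
#' A parsed radiology-report age statement: either a point label
#' ("approximately 9 years old") or an interval label ("12-13 years old").
#' Bounds are stored in months; for point labels the two bounds coincide.
#'
#' @slot kind Either `"point"` or `"interval"`.
#' @slot lowMonths Lower bound in months, in (0, 240].
#' @slot highMonths Upper bound in months; equals `lowMonths` for points.
#' @slot rawText The source text the label was parsed from.
#'
#' @seealso [parseReportLabel()], [labelToMu()]
#' @export
setClass("AmbiguousLabel",
  representation(
    kind = "character",
    lowMonths = "numeric",
    highMonths = "numeric",
    rawText = "character"
  )
)

setValidity("AmbiguousLabel", function(object) {
  msg <- NULL
  if (!object@kind %in% c("point", "interval"))
    msg <- c(msg, "kind must be 'point' or 'interval'")
  if (length(object@lowMonths) != 1L || length(object@highMonths) != 1L)
    msg <- c(msg, "bounds must be scalars")
  else {
    if (!(object@lowMonths > 0 && object@lowMonths <= object@highMonths &&
          object@highMonths <= 240))
      msg <- c(msg, "bounds must satisfy 0 < low <= high <= 240 months")
    if (object@kind == "point" && object@lowMonths != object@highMonths)
      msg <- c(msg, "point labels must have equal bounds")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an ambiguous label
#'
#' @param kind `"point"` or `"interval"`.
#' @param lowMonths,highMonths Bounds in months, `0 < low <= high <= 240`.
#'   `highMonths` defaults to `lowMonths` (point label).
#' @param rawText Optional source text.
#' @return An [AmbiguousLabel-class] object.
#' @examples
#' ambiguousLabel("interval", 144, 156)
#' @export
ambiguousLabel <- function(kind, lowMonths, highMonths = lowMonths,
                           rawText = "") {
  new("AmbiguousLabel", kind = kind, lowMonths = as.numeric(lowMonths),
      highMonths = as.numeric(highMonths), rawText = rawText)
}

setMethod("show", "AmbiguousLabel", function(object) {
  if (object@kind == "point") {
    cat(sprintf("AmbiguousLabel(point, %.6g months", object@lowMonths))
  } else {
    cat(sprintf("AmbiguousLabel(interval, [%.6g, %.6g] months",
                object@lowMonths, object@highMonths))
  }
  if (nzchar(object@rawText)) cat(sprintf(", %s", dQuote(object@rawText)))
  cat(")\n")
})

#' Gaussian label distribution over monthly bins
#'
#' A probability vector over the 240 one-month bone-age classes, built by
#' evaluating a Gaussian density centred at `mu` with spread `sigma` at the
#' bin centres and renormalizing (implicit truncation to (0, 240] months).
#'
#' @slot probs Numeric vector of length 240; non-negative, sums to 1.
#' @slot mu Centre in months.
#' @slot sigma Standard deviation in months.
#'
#' @seealso [makeDistribution()], [decodeAge()]
#' @export
setClass("LabelDistribution",
  representation(probs = "numeric", mu = "numeric", sigma = "numeric")
)

setValidity("LabelDistribution", function(object) {
  msg <- NULL
  if (length(object@probs) != .BONE_AGE_BINS)
    msg <- c(msg, sprintf("probs must have length %d", .BONE_AGE_BINS))
  if (any(object@probs < 0) || any(object@probs > 1))
    msg <- c(msg, "probs must lie in [0, 1]")
  if (abs(sum(object@probs) - 1) > 1e-9)
    msg <- c(msg, "probs must sum to 1 within 1e-9")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "LabelDistribution", function(object) {
  cat(sprintf(
    "LabelDistribution: mu = %.6g months, sigma = %.6g months, mode bin = %d\n",
    object@mu, object@sigma, which.max(object@probs)))
})

#' @describeIn LabelDistribution-class extract the probability vector.
#' @param object A `LabelDistribution`.
#' @export
setGeneric("labelProbs", function(object) standardGeneric("labelProbs"))

#' @rdname LabelDistribution-class
#' @export
setMethod("labelProbs", "LabelDistribution", function(object) object@probs)

#' Per-sample ensemble of epoch predictions
#'
#' Holds the exponential moving average of per-sample predicted distributions
#' across training epochs (temporal ensembling). The assembled matrix `S` is
#' initialized to zeros before the first epoch; the bias-corrected training
#' target is \eqn{\bar Y_{t+1} = S_t / (1 - \gamma^t)}.
#'
#' @slot assembled Numeric matrix, samples x bins; all zeros at epoch 0.
#' @slot gamma Momentum in (0, 1).
#' @slot epoch Number of updates applied so far (t).
#'
#' @seealso [emaUpdate()], [temporalLoss()]
#' @export
setClass("EnsembleState",
  representation(assembled = "matrix", gamma = "numeric", epoch = "integer")
)

setValidity("EnsembleState", function(object) {
  msg <- NULL
  if (!(object@gamma > 0 && object@gamma < 1))
    msg <- c(msg, "gamma must lie in (0, 1)")
  if (object@epoch < 0L) msg <- c(msg, "epoch must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct an empty ensemble state
#'
#' @param nSamples Number of tracked samples.
#' @param gamma Momentum coefficient in (0, 1). Default 0.6.
#' @param nBins Number of label bins (default [boneAgeBins()]).
#' @return An [EnsembleState-class] at epoch 0 with zero-initialized
#'   assembled predictions.
#' @export
ensembleState <- function(nSamples, gamma = 0.6, nBins = boneAgeBins()) {
  new("EnsembleState",
      assembled = matrix(0, nrow = nSamples, ncol = nBins),
      gamma = gamma, epoch = 0L)
}

setMethod("show", "EnsembleState", function(object) {
  cat(sprintf("EnsembleState: %d samples, gamma = %.3g, epoch = %d\n",
              nrow(object@assembled), object@gamma, object@epoch))
})

#' Trained multibranch bone-age model
#'
#' Bundles everything needed to resume training or predict: the (fixed)
#' backbone weights, the trainable 1x1 projection, the frozen per-channel
#' feature standardization, per-branch ensemble states, the optimizer
#' momentum buffer, the resolved configuration, the epoch counter, the seed
#' and the RNG state at the last completed epoch.
#'
#' @slot backbone List of convolution kernels of the feature extractor.
#' @slot projection K x C matrix of 1x1-convolution weights used for
#'   prediction: the validation-best head when a validation set was given,
#'   otherwise the final head.
#' @slot featNorm List with per-channel `mean` and `sd` used to standardize
#'   backbone features before projection.
#' @slot config Resolved training configuration (list, see [baaConfig()]).
#' @slot states List of per-branch [EnsembleState-class] objects
#'   (`raw`, `hand`).
#' @slot trainState List with the optimizer's current `projection`, momentum
#'   buffer `velocity`, the RNG state at the last completed epoch, and the
#'   running best-validation record — everything needed to resume training
#'   bit-identically.
#' @slot epoch Completed training epochs.
#' @slot seed Integer seed the run was started from.
#' @slot lossLog Data frame with one row per epoch:
#'   `epoch, L_raw, L_hand, L_parts, T_t, L_total, val_mae`.
#'
#' @seealso [trainBoneAge()], [predictAge()]
#' @export
setClass("BoneAgeModel",
  representation(
    backbone = "list",
    projection = "matrix",
    featNorm = "list",
    config = "list",
    states = "list",
    trainState = "list",
    epoch = "integer",
    seed = "integer",
    lossLog = "data.frame"
  )
)

setMethod("show", "BoneAgeModel", function(object) {
  cat(sprintf(
    "BoneAgeModel: %d epochs trained, K = %d feature channels, C = %d bins\n",
    object@epoch, nrow(object@projection), ncol(object@projection)))
  if (nrow(object@lossLog) > 0) {
    last <- object@lossLog[nrow(object@lossLog), ]
    cat(sprintf("  last epoch loss: total %.4f (raw %.4f, hand %.4f, parts %.4f)\n",
                last$L_total, last$L_raw, last$L_hand, last$L_parts))
    if (is.finite(last$val_mae))
      cat(sprintf("  last validation MAE: %.2f months\n", last$val_mae))
  }
})

#' @describeIn BoneAgeModel-class per-epoch loss log.
#' @param object A `BoneAgeModel`.
#' @export
setGeneric("lossLog", function(object) standardGeneric("lossLog"))

#' @rdname BoneAgeModel-class
#' @export
setMethod("lossLog", "BoneAgeModel", function(object) object@lossLog)

#' @describeIn BoneAgeModel-class resolved configuration of the run.
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' @rdname BoneAgeModel-class
#' @export
setMethod("modelConfig", "BoneAgeModel", function(object) object@config)
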
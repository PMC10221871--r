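## Label codec: radiology-report age statements -> Gaussian label
## distributions over 240 monthly bins, and back to a scalar age.

.parseError <- function(text) {
  stop(structure(
    class = c("baa_parse_error", "error", "condition"),
    list(message = sprintf("cannot parse age statement: %s", dQuote(text)),
         call = sys.call(-1), text = text)))
}

.num <- "([0-9]+(?:\\.[0-9]+)?)"

#' Parse an ambiguous age statement from a radiology report
#'
#' Recognizes English point patterns ("approximately 9 years old",
#' "about 2 years", "30 months", bare "9 years") and interval patterns
#' ("12-13 years old" with hyphen or en/em dash, "between 13 and 14",
#' "13 to 14 years"). Years are converted to months. Text that contains no
#' age pattern raises a condition of class `baa_parse_error` carrying the
#' offending text — never a silent default.
#'
#' @param text Non-empty character scalar.
#' @return An [AmbiguousLabel-class].
#' @examples
#' parseReportLabel("approximately 9 years old")
#' parseReportLabel("12–13 years old")
#' @export
parseReportLabel <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("text must be a non-empty character scalar")
  s <- tolower(trimws(text))
  s <- gsub("[–—]", "-", s)  # en/em dash -> hyphen

  asMonths <- function(value, unit) {
    if (is.na(unit) || !nzchar(unit) || startsWith(unit, "year")) value * 12
    else value
  }
  finish <- function(kind, low, high) {
    if (!(low > 0 && low <= high && high <= 240)) .parseError(text)
    ambiguousLabel(kind, low, high, rawText = text)
  }

  # interval: "between 13 and 14 (years)", "aged between ..."
  m <- regmatches(s, regexec(
    paste0("between\\s+", .num, "\\s+and\\s+", .num,
           "\\s*(years?|months?)?"), s))[[1]]
  if (length(m)) {
    u <- m[4]
    return(finish("interval", asMonths(as.numeric(m[2]), u),
                  asMonths(as.numeric(m[3]), u)))
  }
  # interval: "12-13 years", "13 to 14 years"
  m <- regmatches(s, regexec(
    paste0(.num, "\\s*(?:-|to\\s)\\s*", .num,
           "\\s*(years?|months?)"), s))[[1]]
  if (length(m)) {
    u <- m[4]
    return(finish("interval", asMonths(as.numeric(m[2]), u),
                  asMonths(as.numeric(m[3]), u)))
  }
  # point: optional qualifier, number, unit
  m <- regmatches(s, regexec(
    paste0("(?:approximately|about|around|roughly|~)?\\s*", .num,
           "\\s*(years?|months?)(?:\\s+old)?"), s))[[1]]
  if (length(m)) {
    v <- asMonths(as.numeric(m[2]), m[3])
    return(finish("point", v, v))
  }
  .parseError(text)
}

#' Reduce an ambiguous label to a distribution centre
#'
#' Point labels map to their value; interval labels map to the interval
#' midpoint, matching the convention that "12-13 years old" stands for about
#' 150 months.
#'
#' @param label An [AmbiguousLabel-class].
#' @return Centre `mu` in months.
#' @examples
#' labelToMu(parseReportLabel("12–13 years old"))  # 150
#' @export
labelToMu <- function(label) {
  stopifnot(is(label, "AmbiguousLabel"))
  if (label@kind == "point") label@lowMonths
  else (label@lowMonths + label@highMonths) / 2
}

#' Build a Gaussian label distribution over monthly bins
#'
#' Evaluates the Gaussian density \eqn{\phi(l_i; \mu, \sigma)} at the bin
#' centres \eqn{l_i = i}, \eqn{i = 1..240} months, and renormalizes so the
#' probabilities sum to one (implicit truncation to the label range).
#'
#' @param mu Centre in months, in (0, 240].
#' @param sigma Standard deviation in months, > 0. Default 3 (the spread at
#'   which the hand branch performs best; roughly matched to expert
#'   inter-rater error).
#' @return A [LabelDistribution-class].
#' @examples
#' d <- makeDistribution(108, 3)
#' sum(labelProbs(d))  # 1
#' @export
makeDistribution <- function(mu, sigma = 3) {
  if (!is.numeric(mu) || length(mu) != 1L || !(mu > 0 && mu <= 240))
    stop("mu must be a single value in (0, 240] months")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive value")
  bins <- seq_len(boneAgeBins())
  p <- stats::dnorm(bins, mean = mu, sd = sigma)
  p <- p / sum(p)
  new("LabelDistribution", probs = p, mu = mu, sigma = sigma)
}

#' Decode a predicted label distribution to an age in months
#'
#' The default readout is the expectation \eqn{\sum_i p_i l_i} over the
#' monthly bins (standard in label-distribution age estimation); `"argmax"`
#' returns the mode bin instead.
#'
#' @param dist A [LabelDistribution-class] or a numeric probability vector of
#'   length 240 summing to 1 within 1e-6.
#' @param method `"expectation"` (default) or `"argmax"`.
#' @return Age in months.
#' @examples
#' decodeAge(makeDistribution(120, 3))  # 120
#' @export
decodeAge <- function(dist, method = c("expectation", "argmax")) {
  method <- match.arg(method)
  p <- if (is(dist, "LabelDistribution")) dist@probs else as.numeric(dist)
  if (length(p) != boneAgeBins())
    stop(sprintf("expected %d bin probabilities", boneAgeBins()))
  if (abs(sum(p) - 1) > 1e-6)
    stop("probabilities must sum to 1 within 1e-6")
  bins <- seq_along(p)
  switch(method,
    expectation = sum(p * bins),
    argmax = bins[which.max(p)])
}
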
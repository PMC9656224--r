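#' @name peripheral-features
#' @title Time-domain statistical descriptors for peripheral channels
#' @description
#' Each peripheral physiological channel (EOG, EMG, GSR, respiration,
#' plethysmograph, temperature) is summarized per analysis window by 12
#' time-domain statistics, in this fixed order: mean, variance, standard
#' deviation, max, min, skewness, kurtosis, 25%/50%/75% quantiles,
#' zero-crossing rate and approximate entropy. Moments are population
#' (divide by N) and kurtosis is excess kurtosis; both conventions are
#' immaterial at the 512-sample windows the pipeline uses but are fixed so
#' features are comparable across implementations.
NULL

PERIPHERAL_STAT_NAMES <- c("mean", "variance", "std", "max", "min",
                           "skewness", "kurtosis", "q25", "q50", "q75",
                           "zcr", "apen")

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Ten basic distribution statistics of a signal
#'
#' @param x Numeric vector, length >= 2.
#' @return Named numeric vector: mean, variance (population), std
#'   (population), max, min, skewness, kurtosis (excess), q25, q50, q75
#'   (linear-interpolation quantiles). Constant signals return 0 skewness
#'   and kurtosis rather than NaN.
#' @export
basic_stats <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L, all(is.finite(x)))
  mu <- mean(x)
  d <- x - mu
  v <- mean(d^2)
  s <- sqrt(v)
  if (s > 0) {
    skew <- mean(d^3) / s^3
    kurt <- mean(d^4) / s^4 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  c(mean = mu, variance = v, std = s, max = max(x), min = min(x),
    skewness = skew, kurtosis = kurt, q25 = q[1L], q50 = q[2L], q75 = q[3L])
}

#' Zero-crossing rate of the mean-centred signal
#'
#' Strict sign changes of `x - mean(x)` divided by `N - 1`. Exact zeros
#' after centring inherit the previous nonzero sign, so grazing the mean
#' does not count as a crossing. Centring matters for channels with large
#' DC offsets (e.g. skin temperature), whose raw ZCR would be identically 0.
#'
#' @param x Numeric vector, length >= 2.
#' @return Rate in \[0, 1\].
#' @export
zero_crossing_rate <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L, all(is.finite(x)))
  s <- sign(x - mean(x))
  for (i in seq_along(s)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
  s <- s[s != 0]
  if (length(s) < 2L) return(0)
  sum(s[-1L] * s[-length(s)] < 0) / (length(x) - 1L)
}

#' Approximate entropy of a signal
#'
#' ApEn(m, r) = Phi_m(r) - Phi_{m+1}(r), where Phi_m is the average log
#' fraction of m-length templates within Chebyshev distance r of each
#' template (self-matches included). Low values indicate regular,
#' predictable signals; white noise scores high. The tolerance defaults to
#' the field convention r = 0.2 x std(x) (population std); a constant
#' signal (std 0) is perfectly regular and returns 0.
#'
#' @param x Numeric vector, length > m + 1.
#' @param m Template (embedding) length, default 2.
#' @param r Absolute tolerance; default `0.2 * pop_sd(x)`.
#' @return Nonnegative scalar.
#' @export
approximate_entropy <- function(x, m = 2L, r = NULL) {
  stopifnot(is.numeric(x), all(is.finite(x)), m >= 1L, length(x) > m + 1L)
  if (is.null(r)) {
    s <- pop_sd(x)
    if (s == 0) return(0)
    r <- 0.2 * s
  }
  stopifnot(r >= 0)
  apen_cpp(as.numeric(x), as.integer(m), as.numeric(r))
}

#' Peripheral feature block for one window
#'
#' Computes the 12 statistics for every peripheral channel of a window,
#' channels in matrix order (outer loop), statistics in the fixed order
#' (inner loop). With the 8 standard peripheral sensors this yields 96
#' features.
#'
#' @param window An `emo_window` from [slide_windows()], or any object with
#'   a `peripheral` channels-x-samples matrix with rownames.
#' @return Named numeric vector of length `12 * n_channels`, names
#'   `<channel>__<statistic>`.
#' @export
peripheral_feature_vector <- function(window) {
  per <- window$peripheral
  stopifnot(is.matrix(per), nrow(per) >= 1L, !is.null(rownames(per)))
  out <- lapply(rownames(per), function(ch) {
    x <- per[ch, ]
    vals <- tryCatch(
      c(basic_stats(x), zcr = zero_crossing_rate(x),
        apen = approximate_entropy(x)),
      error = function(e) stop("channel '", ch, "': ", conditionMessage(e)))
    names(vals) <- paste0(ch, "__", PERIPHERAL_STAT_NAMES)
    vals
  })
  unlist(out)
}
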
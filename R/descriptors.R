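#' Moment-based skewness
#'
#' The third standardized central moment
#' \eqn{g_1 = m_3 / m_2^{3/2}} with denominator-n ("population") central
#' moments \eqn{m_k = n^{-1} \sum (x_i - \bar x)^k}.  This is the
#' convention of the standard statistics libraries for physiological
#' time-series work; a Gaussian sample has expectation 0.
#'
#' @param x Numeric vector, length >= 3, non-zero variance.
#' @param bias_corrected If `TRUE`, return the bias-corrected sample
#'   statistic \eqn{G_1 = g_1 \sqrt{n(n-1)}/(n-2)}.
#' @param na.rm Drop missing values first.
#' @return A single number.
#' @export
#' @examples
#' skewness(c(1, 2, 3, 4, 5))   # 0: symmetric
#' skewness(rexp(1e4))          # ~ 2
skewness <- function(x, bias_corrected = FALSE, na.rm = FALSE) {
  x <- check_moment_input(x, min_n = 3, na.rm = na.rm)
  n <- length(x)
  d <- x - mean(x)
  m2 <- mean(d^2)
  g1 <- mean(d^3) / m2^1.5
  if (bias_corrected) g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g1
}

#' Moment-based excess kurtosis
#'
#' The fourth standardized central moment minus 3:
#' \eqn{g_2 = m_4 / m_2^2 - 3} with denominator-n central moments, so a
#' Gaussian sample has expectation 0 and the two-point symmetric
#' distribution attains the minimum of -2.
#'
#' @inheritParams skewness
#' @param bias_corrected If `TRUE`, return the bias-corrected
#'   \eqn{G_2 = ((n+1) g_2 + 6)(n-1)/((n-2)(n-3))}.
#' @return A single number.
#' @export
excess_kurtosis <- function(x, bias_corrected = FALSE, na.rm = FALSE) {
  x <- check_moment_input(x, min_n = 4, na.rm = na.rm)
  n <- length(x)
  d <- x - mean(x)
  m2 <- mean(d^2)
  g2 <- mean(d^4) / m2^2 - 3
  if (bias_corrected) g2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  g2
}

check_moment_input <- function(x, min_n, na.rm) {
  x <- as.numeric(x)
  if (na.rm) x <- x[!is.na(x)]
  if (anyNA(x)) stop_ppchron("format", "missing values (use na.rm = TRUE)")
  if (length(x) < min_n) {
    stop_ppchron("insufficient_data",
                 sprintf("need at least %d observations", min_n))
  }
  if (var(x) == 0) {
    stop_ppchron("zero_variance",
                 "statistic undefined for a zero-variance series")
  }
  x
}

#' Sample autocorrelation function (biased estimator)
#'
#' The demeaned, biased (denominator-n, pooled-variance) estimator
#' \deqn{\hat\rho_k = \frac{\sum_{t=1}^{n-k} (x_t - \bar x)(x_{t+k} - \bar x)}
#'                         {\sum_{t=1}^{n} (x_t - \bar x)^2},}
#' which guarantees \eqn{|\hat\rho_k| \le 1} and \eqn{\hat\rho_0 = 1}.
#'
#' @param x Numeric vector with non-zero variance.
#' @param max_lag Largest lag, `max_lag < length(x)` (default 48: two
#'   days of hourly samples).
#' @return Numeric vector of length `max_lag + 1` over lags `0..max_lag`.
#' @export
signal_acf <- function(x, max_lag = 48L) {
  x <- as.numeric(x)
  if (anyNA(x)) stop_ppchron("format", "missing values in `x`")
  n <- length(x)
  if (max_lag >= n || max_lag < 0) {
    stop_ppchron("argument", "`max_lag` must satisfy 0 <= max_lag < length(x)")
  }
  if (n < 2 || var(x) == 0) {
    stop_ppchron("zero_variance", "ACF undefined for a zero-variance series")
  }
  d <- x - mean(x)
  denom <- sum(d^2)
  vapply(0:max_lag, function(k) {
    sum(d[seq_len(n - k)] * d[seq_len(n - k) + k]) / denom
  }, numeric(1))
}

#' Poincare plot descriptors SD1, SD2 and their ratio
#'
#' With lagged copies \eqn{a = (x_2, \dots, x_n)} and
#' \eqn{b = (x_1, \dots, x_{n-1})}, SD1 is the population standard
#' deviation of \eqn{(a - b)/\sqrt 2} (spread perpendicular to the
#' identity line: short-term variability) and SD2 that of
#' \eqn{(a + b)/\sqrt 2} (spread along it: long-term variability).
#' Population (denominator-n) SDs are used so the exact identities
#' \eqn{SD1^2 + SD2^2 = Var(a) + Var(b)} and
#' \eqn{(SD1/SD2)^2 = (\bar V - C)/(\bar V + C)} hold, with
#' \eqn{\bar V = (Var\,a + Var\,b)/2} and \eqn{C = Cov(a, b)} computed
#' with the same denominator.  The ratio is flagged undefined (`NA`)
#' when SD2 = 0.
#'
#' @param x Numeric vector, length >= 3.
#' @return A list with elements `sd1`, `sd2`, `ratio`.
#' @export
#' @examples
#' poincare(sin(1:100))
poincare <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop_ppchron("format", "missing values in `x`")
  if (length(x) < 3) {
    stop_ppchron("insufficient_data", "need at least 3 points")
  }
  a <- x[-1]
  b <- x[-length(x)]
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  sd1 <- pop_sd((a - b) / sqrt(2))
  sd2 <- pop_sd((a + b) / sqrt(2))
  list(sd1 = sd1, sd2 = sd2,
       ratio = if (sd2 == 0) NA_real_ else sd1 / sd2)
}

#' Area under the intensity-time curve
#'
#' Trapezoidal integral of intensity over time (hours), the total
#' production of the monitored volatile over the observation window.
#' Negative intensities (possible after noise subtraction) are included
#' as-is.
#'
#' @param x A [chronogram()], or a numeric time vector when
#'   `intensities` is given.
#' @param intensities Intensities matching `x` (default method only).
#' @param ... Unused.
#' @return A single number, intensity x hours.
#' @export
#' @examples
#' auc(chronogram(0:2, c(0, 1, 0)))  # 1
auc <- function(x, ...) UseMethod("auc")

#' @rdname auc
#' @export
auc.chronogram <- function(x, ...) auc.default(x$times, x$intensities)

#' @rdname auc
#' @export
auc.default <- function(x, intensities, ...) {
  times <- as.numeric(x)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities)) {
    stop_ppchron("format", "`x` and `intensities` must have equal length")
  }
  if (length(times) < 2) {
    stop_ppchron("insufficient_data", "need at least 2 points to integrate")
  }
  if (any(diff(times) <= 0)) {
    stop_ppchron("format", "`times` must be strictly increasing")
  }
  if (anyNA(intensities)) {
    stop_ppchron("format", "missing intensities")
  }
  sum(diff(times) * (head(intensities, -1) + tail(intensities, -1)) / 2)
}

#' Equal-width value histogram
#'
#' Bins span `[min(x), max(x)]`; bins are left-closed with the rightmost
#' bin closed on both sides, so counts always sum to `length(x)`.  An
#' all-equal vector yields a single unit-width bin centred on the value.
#'
#' @param x Non-empty numeric vector.
#' @param n_bins Number of bins (default 30).
#' @return A list with `edges` (length `n_bins + 1`) and `counts`
#'   (length `n_bins`).
#' @export
intensity_histogram <- function(x, n_bins = 30L) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  if (!length(x)) stop_ppchron("empty_input", "`x` is empty")
  if (n_bins < 1) stop_ppchron("argument", "`n_bins` must be >= 1")
  lo <- min(x); hi <- max(x)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  idx <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  list(edges = edges, counts = tabulate(idx, nbins = n_bins))
}

#' Compute the full homeostasis descriptor suite of a chronogram
#'
#' Populates every descriptor used by the homeostasis analysis —
#' statistical moments, autocorrelation function, Poincare SD1/SD2,
#' value histogram, area under the curve — for one chronogram
#' (conventionally the biological-mean series).  Descriptors that are
#' undefined for the input (e.g. moments of a constant series) are
#' recorded as `NA` together with the failure message in `$errors`
#' rather than aborting the whole suite.
#'
#' @param chron A [chronogram()].
#' @param max_lag Largest ACF lag (default 48).
#' @param n_bins Histogram bin count (default 30).
#' @param na.rm Drop `NA` intensities (e.g. interpolation-flagged gaps
#'   excluded upstream) before computing.
#' @return An object of class `descriptor_set` with fields `n_points`,
#'   `mean_intensity`, `sd_intensity`, `skewness`, `excess_kurtosis`,
#'   `acf` (lags `0..max_lag`), `acf1`, `sd1`, `sd2`, `sd_ratio`, `auc`,
#'   `histogram`, `condition`, `errors`.
#' @export
describe <- function(chron, max_lag = 48L, n_bins = 30L, na.rm = FALSE) {
  if (!is_chronogram(chron)) {
    stop_ppchron("format", "`chron` must be a chronogram")
  }
  x <- chron$intensities
  t <- chron$times
  if (na.rm) { keep <- !is.na(x); x <- x[keep]; t <- t[keep] }
  errors <- list()
  grab <- function(name, expr) {
    tryCatch(expr, ppchron_error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  max_lag <- min(max_lag, length(x) - 1L)
  sk <- grab("skewness", skewness(x))
  ku <- grab("excess_kurtosis", excess_kurtosis(x))
  ac <- grab("acf", signal_acf(x, max_lag))
  pc <- grab("poincare", poincare(x))
  area <- grab("auc", auc.default(t, x))
  hist <- grab("histogram", intensity_histogram(x, n_bins))
  structure(
    list(
      n_points = length(x),
      mean_intensity = mean(x),
      sd_intensity = sd(x),
      skewness = sk %||% NA_real_,
      excess_kurtosis = ku %||% NA_real_,
      acf = ac,
      acf1 = if (!is.null(ac) && length(ac) > 1) ac[2] else NA_real_,
      sd1 = if (is.null(pc)) NA_real_ else pc$sd1,
      sd2 = if (is.null(pc)) NA_real_ else pc$sd2,
      sd_ratio = if (is.null(pc)) NA_real_ else pc$ratio,
      auc = area %||% NA_real_,
      histogram = hist,
      condition = chron$condition,
      errors = errors
    ),
    class = "descriptor_set"
  )
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> %s (n = %d)\n", x$condition, x$n_points))
  cat(sprintf(
    "  skewness %.3f | excess kurtosis %.3f | lag-1 ACF %.3f\n",
    x$skewness, x$excess_kurtosis, x$acf1
  ))
  cat(sprintf(
    "  SD1 %.4g | SD2 %.4g | SD1/SD2 %.4f | AUC %.4g\n",
    x$sd1, x$sd2, x$sd_ratio, x$auc
  ))
  if (length(x$errors)) {
    cat("  undefined:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
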
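#' Detect a signal above the background noise level
#'
#' A target-ion signal counts as detected when its mean intensity
#' exceeds the background mean by more than `k` background standard
#' deviations — the classical "above white noise" criterion.
#'
#' @param signal,background [chronogram()] objects (conventionally
#'   biological means).
#' @param k Detection multiplier (default 3).
#' @return `TRUE` or `FALSE`.
#' @export
detect_above_noise <- function(signal, background, k = 3) {
  if (!is_chronogram(signal) || !is_chronogram(background)) {
    stop_ppchron("format", "`signal` and `background` must be chronograms")
  }
  bg <- background$intensities[!is.na(background$intensities)]
  if (length(bg) < 2 || sd(bg) == 0) {
    stop_ppchron("degenerate_background",
                 "background chronogram has zero variance")
  }
  mean(signal$intensities, na.rm = TRUE) > mean(bg) + k * sd(bg)
}

#' Hour-of-day emission profile and day/night contrast
#'
#' Maps each sample of a chronogram to its clock hour (from the
#' inoculation clock time), averages intensity by hour of day, and
#' reports the peak hour and the dark/light mean ratio under the
#' configured photoperiod.  "Night" is the lights-off phase (8 h of the
#' 16:8 photoperiod by default), not astronomical night.
#'
#' @param chron A [chronogram()] spanning at least 48 h.
#' @param lights_on_hour,lights_off_hour Photoperiod clock hours
#'   (defaults 4 and 20: dark phase 20:00-04:00).
#' @param inoculation_clock_hour Clock time of `time_h = 0`
#'   (default 8, 08:00).
#' @return An object of class `circadian_summary`: list with
#'   `hour_of_day_profile` (named 24-vector, hours `0..23`),
#'   `peak_hour` (argmax, ties broken to the earliest hour), and
#'   `night_day_ratio` (mean over dark hours / mean over light hours).
#' @export
circadian_summary <- function(chron, lights_on_hour = 4, lights_off_hour = 20,
                              inoculation_clock_hour = 8) {
  if (!is_chronogram(chron)) {
    stop_ppchron("format", "`chron` must be a chronogram")
  }
  if (diff(range(chron$times)) < 48) {
    stop_ppchron("insufficient_span",
                 "need at least 48 h of data for an hour-of-day profile")
  }
  hr <- floor((inoculation_clock_hour + chron$times) %% 24)
  prof <- vapply(0:23, function(h) {
    mean(chron$intensities[hr == h], na.rm = TRUE)
  }, numeric(1))
  names(prof) <- 0:23
  peak <- (0:23)[which.max(prof)]   # which.max takes the first maximum
  dark <- is_dark_hour(0:23, lights_on_hour, lights_off_hour) == 1
  ratio <- mean(prof[dark], na.rm = TRUE) / mean(prof[!dark], na.rm = TRUE)
  structure(
    list(hour_of_day_profile = prof, peak_hour = peak,
         night_day_ratio = ratio),
    class = "circadian_summary"
  )
}

#' @export
print.circadian_summary <- function(x, ...) {
  cat(sprintf(
    "<circadian_summary> peak at %02d:00 | night/day ratio %.3f\n",
    x$peak_hour, x$night_day_ratio
  ))
  invisible(x)
}

#' Production fold change between two conditions
#'
#' Ratio of the areas under the biological-mean intensity curves,
#' `auc(a) / auc(b)` — total production of condition `a` relative to
#' condition `b`.
#'
#' @param a,b [chronogram()] objects.
#' @return A single number.
#' @export
production_fold_change <- function(a, b) {
  denom <- auc(b)
  if (denom <= 0) {
    stop_ppchron("undefined_ratio",
                 "reference AUC must be positive for a fold change")
  }
  auc(a) / denom
}
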
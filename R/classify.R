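#' Thresholds for the background / physiological / stabilized rule table
#'
#' The homeostasis framework distinguishes *physiological* variables
#' (high variability, heavy-tailed, adaptive) from *regulated* ones
#' (tightly controlled, near-Gaussian).  The verbal criteria — "high"
#' skewness, "high" autocorrelation — need explicit numeric thresholds;
#' these are deliberately a mandatory argument of [classify_variable()]
#' so an analysis always states the thresholds it used.
#'
#' @param s0 Skewness above which a detected signal counts as
#'   heavy-tailed (default 1).
#' @param k0 Excess kurtosis above which a detected signal counts as
#'   heavy-tailed (default 3).
#' @param reduction Minimum relative reduction of skewness or kurtosis
#'   (vs the physiological reference) that signals stabilization
#'   (default 0.25, i.e. 25%).
#' @param acf_delta Slack added to the background lag-1 ACF when testing
#'   whether a signal's autocorrelation is still "background-like"
#'   (default 0.3).
#' @param k_detect Detection multiplier for the above-noise criterion
#'   (default 3).
#' @return An object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(s0 = 1, k0 = 3, reduction = 0.25,
                                      acf_delta = 0.3, k_detect = 3) {
  th <- list(s0 = s0, k0 = k0, reduction = reduction,
             acf_delta = acf_delta, k_detect = k_detect)
  if (any(!vapply(th, function(v) is.numeric(v) && is.finite(v), logical(1)))) {
    stop_ppchron("configuration", "all thresholds must be finite numbers")
  }
  structure(th, class = "classification_thresholds")
}

#' Classify a signal as background, physiological, or stabilized
#'
#' Applies the documented rule table to a descriptor set, a background
#' descriptor set, and (optionally) a physiological reference:
#'
#' 1. Not detected above background noise (mean <= background mean +
#'    `k_detect` x background SD) -> **background**.
#' 2. Detected, a reference is given, the moments are reduced at least
#'    `reduction`-fold relative to the reference (skewness *or*
#'    kurtosis) or both lie below `s0`/`k0`, *and* the lag-1 ACF exceeds
#'    the reference's -> **stabilized**.
#' 3. Detected, skewness > `s0`, excess kurtosis > `k0`, and lag-1 ACF
#'    at most the background's + `acf_delta` -> **physiological**.
#' 4. Otherwise: **physiological** when both moments exceed `s0`/`k0`
#'    (heavy-tailed but strongly autocorrelated), else **stabilized**.
#'
#' The classification is a pure function of its inputs; the returned
#' evidence table records every comparison made.
#'
#' @param d [describe()] output for the signal under scrutiny.
#' @param background [describe()] output for the background condition.
#' @param thresholds A [classification_thresholds()] object (mandatory:
#'   there are no hidden defaults inside the classifier).
#' @param reference Optional [describe()] output of a physiological
#'   reference series (e.g. the fungus-alone condition when classifying
#'   the interaction).
#' @return An object of class `classification_result`: list with
#'   `label`, `evidence` (data frame: criterion, value, threshold,
#'   passed), and `thresholds_used`.
#' @export
classify_variable <- function(d, background, thresholds, reference = NULL) {
  if (!inherits(d, "descriptor_set") || !inherits(background, "descriptor_set")) {
    stop_ppchron("format", "`d` and `background` must be descriptor_set objects")
  }
  if (!inherits(thresholds, "classification_thresholds")) {
    stop_ppchron("configuration",
                 "`thresholds` must be built with classification_thresholds()")
  }
  needed <- c("mean_intensity", "skewness", "excess_kurtosis", "acf1")
  miss <- needed[vapply(needed, function(f) is.na(d[[f]]), logical(1))]
  if (length(miss)) {
    stop_ppchron("incomplete_evidence", sprintf(
      "descriptor(s) unavailable for classification: %s",
      paste(miss, collapse = ", ")
    ))
  }
  if (is.na(background$mean_intensity) || is.na(background$sd_intensity) ||
      background$sd_intensity == 0) {
    stop_ppchron("degenerate_background",
                 "background descriptors missing or zero-variance")
  }
  th <- thresholds
  ev <- list()
  note <- function(criterion, value, threshold, passed) {
    ev[[length(ev) + 1L]] <<- data.frame(
      criterion = criterion, value = value, threshold = threshold,
      passed = passed
    )
  }

  detect_limit <- background$mean_intensity +
    th$k_detect * background$sd_intensity
  detected <- d$mean_intensity > detect_limit
  note("detected_above_noise", d$mean_intensity, detect_limit, detected)

  heavy_skew <- d$skewness > th$s0
  heavy_kurt <- d$excess_kurtosis > th$k0
  note("skewness_high", d$skewness, th$s0, heavy_skew)
  note("kurtosis_high", d$excess_kurtosis, th$k0, heavy_kurt)
  acf_bg_like <- d$acf1 <= background$acf1 + th$acf_delta
  note("acf1_background_like", d$acf1, background$acf1 + th$acf_delta,
       acf_bg_like)

  stabilized <- FALSE
  if (!is.null(reference)) {
    if (!inherits(reference, "descriptor_set")) {
      stop_ppchron("format", "`reference` must be a descriptor_set")
    }
    red_skew <- 1 - d$skewness / reference$skewness
    red_kurt <- 1 - d$excess_kurtosis / reference$excess_kurtosis
    moments_reduced <- (red_skew >= th$reduction) || (red_kurt >= th$reduction)
    note("moment_reduction_vs_reference", max(red_skew, red_kurt),
         th$reduction, moments_reduced)
    moments_low <- !heavy_skew && !heavy_kurt
    acf_above_ref <- d$acf1 > reference$acf1
    note("acf1_above_reference", d$acf1, reference$acf1, acf_above_ref)
    stabilized <- detected && (moments_reduced || moments_low) && acf_above_ref
  }

  label <- if (!detected) {
    "background"
  } else if (stabilized) {
    "stabilized"
  } else if (heavy_skew && heavy_kurt && acf_bg_like) {
    "physiological"
  } else if (heavy_skew && heavy_kurt) {
    "physiological"   # heavy-tailed but strongly autocorrelated
  } else {
    "stabilized"      # detected, near-Gaussian moments
  }

  structure(
    list(label = label, evidence = do.call(rbind, ev),
         thresholds_used = thresholds),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> label: %s\n", x$label))
  print(x$evidence, row.names = FALSE)
  invisible(x)
}
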
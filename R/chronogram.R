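#' Chronogram: a single-ion intensity time series
#'
#' A chronogram is the intensity-versus-time trace of one target ion under
#' one experimental condition — the direct-monitoring generalization of an
#' extracted-ion chromatogram.  Times are hours since inoculation;
#' intensities are dimensionless relative intensities.
#'
#' @param times Strictly increasing numeric vector, hours since inoculation.
#' @param intensities Numeric vector of the same length.  Must be finite;
#'   `NA` is allowed only for derived series (e.g. a standard-deviation
#'   track at time points covered by fewer than two biological replicates).
#' @param condition Condition label (e.g. `"plant"`, `"fungus"`,
#'   `"interaction"`).
#' @param provenance Free-text provenance: `"raw"`, `"technical-mean"` or
#'   `"biological-mean"`.
#' @param target_mz Target ion m/z (default 167.1, the protonated
#'   6-pentyl-alpha-pyrone ion).
#' @param mz_tolerance Half-width of the extraction window in m/z units.
#' @param bio_rep,tech_rep Optional integer replicate identifiers.
#'
#' @return An object of class `chronogram`: a list with fields `times`,
#'   `intensities`, `condition`, `provenance`, `target_mz`, `mz_tolerance`,
#'   `bio_rep`, `tech_rep`.
#' @export
#' @examples
#' ch <- chronogram(0:5, c(0, 1, 4, 2, 1, 0), condition = "fungus")
#' ch
chronogram <- function(times, intensities, condition = NA_character_,
                       provenance = "raw", target_mz = 167.1,
                       mz_tolerance = 0.5, bio_rep = NA_integer_,
                       tech_rep = NA_integer_) {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities)) {
    stop_ppchron("format", "`times` and `intensities` must have equal length")
  }
  if (length(times) == 0L) {
    stop_ppchron("empty_input", "a chronogram needs at least one point")
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop_ppchron("format", "`times` must be finite and non-missing")
  }
  if (any(diff(times) <= 0)) {
    stop_ppchron("format", "`times` must be strictly increasing")
  }
  if (any(is.nan(intensities) | is.infinite(intensities))) {
    stop_ppchron("format", "`intensities` must be finite (NA allowed)")
  }
  structure(
    list(
      times = times, intensities = intensities,
      condition = as.character(condition), provenance = provenance,
      target_mz = target_mz, mz_tolerance = mz_tolerance,
      bio_rep = as.integer(bio_rep), tech_rep = as.integer(tech_rep)
    ),
    class = "chronogram"
  )
}

#' @export
print.chronogram <- function(x, ...) {
  cat(sprintf(
    "<chronogram> %s | %d points over %.1f h | m/z %.1f +/- %.2f | %s\n",
    x$condition, length(x$times), diff(range(x$times)),
    x$target_mz, x$mz_tolerance, x$provenance
  ))
  cat(sprintf(
    "  intensity: min %.4g, median %.4g, max %.4g\n",
    min(x$intensities, na.rm = TRUE),
    stats::median(x$intensities, na.rm = TRUE),
    max(x$intensities, na.rm = TRUE)
  ))
  invisible(x)
}

#' @export
as.data.frame.chronogram <- function(x, ...) {
  data.frame(
    condition = x$condition, bio_rep = x$bio_rep, tech_rep = x$tech_rep,
    time_h = x$times, intensity = x$intensities
  )
}

#' @export
length.chronogram <- function(x) length(x$times)

is_chronogram <- function(x) inherits(x, "chronogram")
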
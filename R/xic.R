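#' Scan frame: one centroided mass spectrum with acquisition metadata
#'
#' @param time_h Acquisition time, hours since inoculation.
#' @param mz Peak m/z values, sorted ascending.
#' @param intensity Peak intensities, finite and non-negative, same
#'   length as `mz`.
#' @param bio_rep,tech_rep Integer replicate identifiers.
#' @param condition Condition label.
#' @return An object of class `scan_frame`.
#' @export
scan_frame <- function(time_h, mz, intensity, bio_rep = NA_integer_,
                       tech_rep = NA_integer_, condition = NA_character_) {
  if (length(time_h) != 1L || !is.finite(time_h) || time_h < 0) {
    stop_ppchron("format", "`time_h` must be a single non-negative number")
  }
  if (length(mz) != length(intensity)) {
    stop_ppchron("format", "`mz` and `intensity` must have equal length")
  }
  if (length(mz)) {
    if (any(!is.finite(mz)) || any(mz <= 0)) {
      stop_ppchron("format", "`mz` values must be finite and positive")
    }
    if (is.unsorted(mz, strictly = FALSE)) {
      stop_ppchron("format", "peak list must be sorted ascending by m/z")
    }
    if (any(!is.finite(intensity)) || any(intensity < 0)) {
      stop_ppchron("format", "peak intensities must be finite and >= 0")
    }
  }
  structure(
    list(time_h = time_h, mz = as.numeric(mz),
         intensity = as.numeric(intensity),
         bio_rep = as.integer(bio_rep), tech_rep = as.integer(tech_rep),
         condition = as.character(condition)),
    class = "scan_frame"
  )
}

#' Extract a single-ion chronogram from a scan stream
#'
#' For every scan, the chronogram intensity is the sum of all peak
#' intensities whose m/z lies within `tolerance` of `target_mz`
#' (inclusive window).  Scans sharing a time stamp — micro-scans — are
#' averaged into one point.  A stream in which no peak ever falls inside
#' the window yields an all-zero chronogram, not an error: absence of the
#' ion is data.
#'
#' @param scans Non-empty list of [scan_frame()] objects.
#' @param target_mz Target ion m/z (default 167.1).
#' @param tolerance Window half-width in m/z units (default 0.5,
#'   unit-resolution ion trap).
#' @return A [chronogram()] with strictly increasing times.
#' @export
#' @examples
#' s <- scan_frame(0, c(167.05, 180), c(1000, 500))
#' extract_xic(list(s), 167.1, 0.2)$intensities  # 1000
extract_xic <- function(scans, target_mz = 167.1, tolerance = 0.5) {
  if (!length(scans)) {
    stop_ppchron("empty_input", "`scans` must contain at least one scan")
  }
  if (!all(vapply(scans, inherits, logical(1), "scan_frame"))) {
    stop_ppchron("format", "`scans` must be a list of scan_frame objects")
  }
  if (!is.finite(tolerance) || tolerance <= 0) {
    stop_ppchron("configuration", "`tolerance` must be > 0")
  }
  t_raw <- vapply(scans, function(s) s$time_h, numeric(1))
  v_raw <- vapply(scans, function(s) {
    inside <- abs(s$mz - target_mz) <= tolerance
    sum(s$intensity[inside])
  }, numeric(1))
  grp <- match(t_raw, sort(unique(t_raw)))
  times <- sort(unique(t_raw))
  vals <- as.numeric(tapply(v_raw, grp, mean))
  conds <- unique(vapply(scans, function(s) s$condition, character(1)))
  chronogram(
    times, vals,
    condition = if (length(conds) == 1L) conds else NA_character_,
    provenance = "raw", target_mz = target_mz, mz_tolerance = tolerance,
    bio_rep = scans[[1]]$bio_rep, tech_rep = scans[[1]]$tech_rep
  )
}
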
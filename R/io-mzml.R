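#' Read centroided mzML scans into scan frames
#'
#' Thin wrapper over the `mzR` reader for the optional raw-data route:
#' each MS1 spectrum becomes a [scan_frame()] whose time is the retention
#' time converted to hours since inoculation.  `mzR` normalizes retention
#' times to seconds regardless of the unit declared in the file, so
#' minute-based files need no special handling.
#'
#' @param path Path to a well-formed centroided mzML file.
#' @param condition Condition label attached to every scan.
#' @param bio_rep,tech_rep Replicate identifiers attached to every scan.
#' @param rt_offset_h Declared inoculation offset, hours: the time of the
#'   first possible scan relative to inoculation (added to the converted
#'   retention times; default 0, acquisition started at inoculation).
#' @return A list of [scan_frame()] objects, ordered by retention time.
#' @export
read_mzml_scans <- function(path, condition = NA_character_,
                            bio_rep = NA_integer_, tech_rep = NA_integer_,
                            rt_offset_h = 0) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop_ppchron("io", "reading mzML requires the `mzR` package")
  }
  if (!file.exists(path)) {
    stop_ppchron("io", sprintf("file not found: %s", path))
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (!nrow(hdr)) {
    stop_ppchron("empty_input", "mzML file contains no spectra")
  }
  if (anyNA(hdr$retentionTime)) {
    stop_ppchron("format", "spectra without retention times")
  }
  if ("centroided" %in% names(hdr) &&
      any(!is.na(hdr$centroided) & !hdr$centroided)) {
    stop_ppchron("unsupported_mode",
                 "profile-mode spectra are not supported; centroid the data first")
  }
  ord <- order(hdr$retentionTime)
  lapply(ord, function(i) {
    pk <- mzR::peaks(handle, hdr$seqNum[i])
    pk <- pk[order(pk[, 1]), , drop = FALSE]
    scan_frame(
      time_h = hdr$retentionTime[i] / 3600 + rt_offset_h,
      mz = pk[, 1], intensity = pk[, 2],
      bio_rep = bio_rep, tech_rep = tech_rep, condition = condition
    )
  })
}
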
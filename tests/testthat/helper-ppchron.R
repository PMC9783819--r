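# Shared helpers: tiny deterministic fixtures built in code.

# A minimal centroided mzML document written by hand (XML + base64-encoded
# little-endian doubles), used to exercise the mzR-backed reader without
# shipping binary fixtures.  `scans` is a list of list(rt = seconds,
# mz = ..., intensity = ...); `rt_unit` switches the declared CV unit.
write_demo_mzml <- function(path, scans, rt_unit = c("second", "minute")) {
  rt_unit <- match.arg(rt_unit)
  unit_acc <- if (rt_unit == "second") "UO:0000010" else "UO:0000031"
  enc64 <- function(v) {
    jsonlite::base64_enc(writeBin(as.double(v), raw(), size = 8,
                                  endian = "little"))
  }
  spec <- vapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    mz64 <- enc64(s$mz); in64 <- enc64(s$intensity)
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%f"',
      ' unitCvRef="UO" unitAccession="%s" unitName="%s"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, length(s$mz), s$rt, unit_acc, rt_unit,
      nchar(mz64), mz64, nchar(in64), in64)
  }, character(1))
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2"><cv id="MS" fullName="PSI-MS" URI="x"/>',
    '<cv id="UO" fullName="UO" URI="x"/></cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="sw" version="1">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/>',
    '</software></softwareList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    '<spectrumList count="%d" defaultDataProcessingRef="dp">%s</spectrumList>',
    '</run></mzML>'),
    length(scans), paste(spec, collapse = ""))
  writeLines(doc, path)
  invisible(path)
}

# Small simulated set for structural tests (fast).
tiny_sim <- function(condition = "fungus", seed = 1, ...) {
  cfg <- simulation_config(condition = condition, duration_days = 3,
                           emission_onset_day = 1.5, emission_offset_day = 3,
                           baseline_emission = 0.01, seed = seed, ...)
  suppressWarnings(simulate_replicate_set(cfg))
}
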
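#' Read and write the canonical long-format chronogram table
#'
#' The canonical on-disk form of a replicate set is a UTF-8 CSV with a
#' header row and columns `condition, bio_rep, tech_rep, time_h,
#' intensity` ('.' decimal separator).  Writing and re-reading reproduces
#' all values exactly (doubles are serialized with round-trip precision).
#'
#' @param set A [replicate_set()].
#' @param path CSV file path.
#' @param config Optional [simulation_config()]; when given, a YAML
#'   sidecar `<path>.yaml` recording every parameter and the seed is
#'   written next to the table.
#' @return `write_chronogram_table()` returns `path` invisibly;
#'   `read_chronogram_table()` returns a [replicate_set()] (aggregation
#'   not yet applied).
#' @export
write_chronogram_table <- function(set, path, config = NULL) {
  if (!inherits(set, "replicate_set")) {
    stop_ppchron("format", "`set` must be a replicate_set")
  }
  rows <- do.call(rbind, lapply(set$chronograms, as.data.frame))
  rownames(rows) <- NULL
  readr::write_csv(tibble::as_tibble(rows), path)
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), paste0(path, ".yaml"))
  }
  invisible(path)
}

#' @param condition Optional condition filter for tables holding several
#'   conditions; reading a multi-condition table without a filter is an
#'   error.
#' @rdname write_chronogram_table
#' @export
read_chronogram_table <- function(path, condition = NULL) {
  if (!file.exists(path)) {
    stop_ppchron("io", sprintf("file not found: %s", path))
  }
  # base read.csv parses doubles exactly (readr's parser can be 1 ulp off,
  # which would break the round-trip identity); columns are read as text and
  # converted so malformed cells can be reported with their row.
  tab <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  required <- c("condition", "bio_rep", "tech_rep", "time_h", "intensity")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop_ppchron("format", sprintf(
      "missing column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in c("bio_rep", "tech_rep", "time_h", "intensity")) {
    parsed <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(parsed) | !nzchar(tab[[col]]))
    if (length(bad)) {
      stop_ppchron("format", sprintf(
        "non-numeric or missing `%s` in row %d (value %s)",
        col, bad[1], sQuote(tab[[col]][bad[1]])
      ))
    }
    tab[[col]] <- if (col %in% c("bio_rep", "tech_rep")) {
      as.integer(parsed)
    } else {
      parsed
    }
  }
  if (!is.null(condition)) {
    tab <- tab[tab$condition == condition, , drop = FALSE]
    if (!nrow(tab)) {
      stop_ppchron("empty_input",
                   sprintf("no rows for condition %s", sQuote(condition)))
    }
  } else if (length(unique(tab$condition)) > 1L) {
    stop_ppchron("format", sprintf(
      "table holds several conditions (%s); pass `condition` to select one",
      paste(unique(tab$condition), collapse = ", ")
    ))
  }
  key <- interaction(tab$condition, tab$bio_rep, tab$tech_rep, drop = TRUE)
  dup <- duplicated(data.frame(key, tab$time_h))
  if (any(dup)) {
    stop_ppchron("format", sprintf(
      "duplicated (replicate, time) entry at row %d (time_h = %g)",
      which(dup)[1], tab$time_h[which(dup)[1]]
    ))
  }
  chrons <- lapply(split(seq_len(nrow(tab)), key), function(idx) {
    sub <- tab[idx, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    chronogram(sub$time_h, sub$intensity, condition = sub$condition[1],
               provenance = "raw", bio_rep = sub$bio_rep[1],
               tech_rep = sub$tech_rep[1])
  })
  replicate_set(unname(chrons))
}
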
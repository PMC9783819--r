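#' Replicate set: the biological x technical chronogram hierarchy
#'
#' Bundles the raw chronograms of one condition, keyed by
#' `(bio_rep, tech_rep)`, together with the derived biological-mean and
#' standard-deviation series once [aggregate_replicates()] has been run.
#'
#' @param chronograms A list of [chronogram()] objects.  Chronograms
#'   without replicate identifiers are assigned sequential biological
#'   replicate numbers (technical replicate 1).
#' @param condition Condition label; defaults to the (single) condition
#'   of the members.
#' @return An object of class `replicate_set`: a list with fields
#'   `chronograms` (named `b<i>_t<j>`), `condition`, `mean`, `sd` (the
#'   latter two `NULL` until aggregation).
#' @export
replicate_set <- function(chronograms, condition = NULL) {
  if (!length(chronograms) || !all(vapply(chronograms, is_chronogram, logical(1)))) {
    stop_ppchron("empty_input", "`chronograms` must be a non-empty list of chronogram objects")
  }
  conds <- unique(vapply(chronograms, function(ch) ch$condition, character(1)))
  if (is.null(condition)) {
    if (length(conds) > 1L) {
      stop_ppchron("format", sprintf(
        "chronograms mix conditions (%s); supply `condition` or split them",
        paste(conds, collapse = ", ")
      ))
    }
    condition <- conds
  }
  for (i in seq_along(chronograms)) {
    if (is.na(chronograms[[i]]$bio_rep)) chronograms[[i]]$bio_rep <- i
    if (is.na(chronograms[[i]]$tech_rep)) chronograms[[i]]$tech_rep <- 1L
  }
  keys <- vapply(chronograms, function(ch) {
    sprintf("b%d_t%d", ch$bio_rep, ch$tech_rep)
  }, character(1))
  if (anyDuplicated(keys)) {
    stop_ppchron("format", sprintf(
      "duplicated replicate key(s): %s",
      paste(unique(keys[duplicated(keys)]), collapse = ", ")
    ))
  }
  names(chronograms) <- keys
  structure(
    list(chronograms = chronograms, condition = condition,
         mean = NULL, sd = NULL),
    class = "replicate_set"
  )
}

#' @export
print.replicate_set <- function(x, ...) {
  bios <- unique(vapply(x$chronograms, function(ch) ch$bio_rep, integer(1)))
  cat(sprintf(
    "<replicate_set> %s | %d chronograms (%d biological) | %s\n",
    x$condition, length(x$chronograms), length(bios),
    if (is.null(x$mean)) "not aggregated" else "aggregated (mean +/- SD)"
  ))
  invisible(x)
}

#' Aggregate technical and biological replicates into mean and SD series
#'
#' Technical replicates are averaged within each biological replicate
#' first; the biological-replicate mean and sample standard deviation
#' (denominator n - 1) are then computed pointwise.  The averaging order
#' is fixed because it defines the SD semantics: the reported SD is the
#' variability between biological samples.
#'
#' Member chronograms are aligned on a common grid by rounding times to
#' the nominal sampling interval; grid points missing from some replicate
#' are filled by linear interpolation and flagged (see the
#' `"interpolated"` attribute of the mean chronogram).  Time points
#' covered by fewer than two biological replicates get `NA` standard
#' deviation and a warning.
#'
#' @param set A [replicate_set()].
#' @param interval Nominal sampling interval in hours; inferred from the
#'   data (median time step) when `NULL`.
#' @return The same `replicate_set` with `mean` and `sd` chronograms
#'   filled in (provenance `"biological-mean"` / `"biological-sd"`).
#' @export
aggregate_replicates <- function(set, interval = NULL) {
  if (!inherits(set, "replicate_set")) {
    stop_ppchron("format", "`set` must be a replicate_set")
  }
  chrons <- set$chronograms
  if (is.null(interval)) {
    steps <- unlist(lapply(chrons, function(ch) diff(ch$times)))
    interval <- if (length(steps)) stats::median(steps) else 1
  }
  aligned <- align_chronograms(chrons, interval)
  grid <- aligned$grid
  vals <- aligned$values      # n_grid x n_chron
  filled <- aligned$filled

  bios <- vapply(chrons, function(ch) ch$bio_rep, integer(1))
  bio_ids <- sort(unique(bios))
  tech_means <- sapply(bio_ids, function(b) {
    rowMeans(vals[, bios == b, drop = FALSE], na.rm = TRUE)
  })
  tech_means <- matrix(tech_means, nrow = length(grid))
  covered <- sapply(bio_ids, function(b) {
    rowSums(!is.na(vals[, bios == b, drop = FALSE])) > 0
  })
  covered <- matrix(covered, nrow = length(grid))

  mean_v <- rowMeans(tech_means, na.rm = TRUE)
  n_bio_at_t <- rowSums(covered)
  sd_v <- apply(tech_means, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) >= 2) sd(r) else NA_real_
  })
  if (any(n_bio_at_t < 2)) {
    warning(sprintf(
      "%d time point(s) covered by fewer than 2 biological replicates; SD reported as NA there",
      sum(n_bio_at_t < 2)
    ), call. = FALSE)
    sd_v[n_bio_at_t < 2] <- NA_real_
  }

  proto <- chrons[[1]]
  set$mean <- chronogram(grid, mean_v, condition = set$condition,
                         provenance = "biological-mean",
                         target_mz = proto$target_mz,
                         mz_tolerance = proto$mz_tolerance)
  attr(set$mean, "interpolated") <- rowSums(filled) > 0
  attr(set$mean, "n_biological") <- n_bio_at_t
  set$sd <- chronogram(grid, sd_v, condition = set$condition,
                       provenance = "biological-sd",
                       target_mz = proto$target_mz,
                       mz_tolerance = proto$mz_tolerance)
  set
}

# Align chronograms on the union grid of interval-rounded times.
# Returns the grid, a value matrix (one column per chronogram) and a
# logical matrix marking interpolation-filled entries.
align_chronograms <- function(chrons, interval) {
  rounded <- lapply(chrons, function(ch) round(ch$times / interval) * interval)
  for (r in rounded) {
    if (anyDuplicated(r)) {
      stop_ppchron("format",
                   "rounding to the sampling interval collapses distinct time points")
    }
  }
  grid <- sort(unique(unlist(rounded)))
  values <- matrix(NA_real_, nrow = length(grid), ncol = length(chrons))
  filled <- matrix(FALSE, nrow = length(grid), ncol = length(chrons))
  for (j in seq_along(chrons)) {
    idx <- match(rounded[[j]], grid)
    values[idx, j] <- chrons[[j]]$intensities
    miss <- which(is.na(values[, j]))
    miss <- miss[grid[miss] >= min(rounded[[j]]) & grid[miss] <= max(rounded[[j]])]
    if (length(miss)) {
      values[miss, j] <- approx(rounded[[j]], chrons[[j]]$intensities,
                                xout = grid[miss])$y
      filled[miss, j] <- TRUE
    }
  }
  list(grid = grid, values = values, filled = filled)
}
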
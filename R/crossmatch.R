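#' Merge isomeric LC features into mass groups
#'
#' Chromatographic features that differ only in retention time are grouped by
#' single-linkage clustering of their m/z within a ppm tolerance; the group
#' mass is the intensity-weighted mean and the multiplicity is the group size.
#' The operation is idempotent.
#'
#' @param lc_features Data frame with columns `mz`, optionally `rt` and
#'   `intensity` (unit weights when absent).
#' @param tol_ppm Merge tolerance in ppm (default 5).
#' @return Data frame: `mz` (group mass), `multiplicity`, `members`
#'   (comma-separated row indices of the input).
#' @export
merge_isomers <- function(lc_features, tol_ppm = 5) {
  stopifnot(is.data.frame(lc_features), "mz" %in% names(lc_features))
  mz <- lc_features$mz
  w <- if ("intensity" %in% names(lc_features)) lc_features$intensity else
    rep(1, length(mz))
  if (length(mz) == 0) {
    return(data.frame(mz = numeric(), multiplicity = integer(),
                      members = character()))
  }
  o <- order(mz)
  gap <- c(Inf, diff(mz[o]) / mz[o][-length(mz)] * 1e6)
  grp <- cumsum(gap > tol_ppm)
  out <- do.call(rbind, lapply(split(seq_along(o), grp), function(k) {
    i <- o[k]
    data.frame(mz = stats::weighted.mean(mz[i], pmax(w[i], 1e-300)),
               multiplicity = length(i),
               members = paste(sort(i), collapse = ","))
  }))
  rownames(out) <- NULL
  out
}

#' Match DI masses against merged LC masses across platforms
#'
#' A pair matches when `|d - l| / ((d + l)/2) * 1e6 <= tol_ppm` (mean
#' denominator, symmetric in the two masses). Matching is many-to-many but
#' each feature is counted once in the overlap fractions.
#'
#' @param di_mzs Numeric vector of direct-infusion feature masses.
#' @param lc_merged Result of [merge_isomers()], or a numeric vector of LC
#'   masses (then treated as already merged with multiplicity 1).
#' @param tol_ppm Match tolerance in ppm (default 5).
#' @return Object of class `"crossmatch_report"`: counts per platform, the
#'   overlap fractions in both directions, the isomer-multiplicity histogram,
#'   and the matched-pair table.
#' @export
match_features <- function(di_mzs, lc_merged, tol_ppm = 5) {
  if (is.numeric(lc_merged)) {
    lc_merged <- data.frame(mz = lc_merged,
                            multiplicity = rep(1L, length(lc_merged)))
  }
  if (length(di_mzs) == 0 || nrow(lc_merged) == 0) stop("empty input")
  di <- sort(di_mzs)
  lc <- lc_merged$mz
  pairs <- list()
  for (j in seq_along(lc)) {
    tol_da <- tol_ppm * 1e-6 * lc[j]      # window; exact rule applied below
    lo <- findInterval(lc[j] - 2 * tol_da, di) + 1L
    hi <- findInterval(lc[j] + 2 * tol_da, di)
    if (hi < lo) next
    for (i in lo:hi) {
      ppm <- abs(di[i] - lc[j]) / ((di[i] + lc[j]) / 2) * 1e6
      if (ppm <= tol_ppm) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(di_mz = di[i], lc_mz = lc[j], error_ppm = ppm)
      }
    }
  }
  pdf <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(di_mz = numeric(), lc_mz = numeric(), error_ppm = numeric())
  hist_tab <- table(factor(lc_merged$multiplicity,
                           levels = seq_len(max(lc_merged$multiplicity))))
  structure(list(
    n_di_features = length(di_mzs),
    n_lc_merged_masses = nrow(lc_merged),
    n_lc_features = sum(lc_merged$multiplicity),
    fraction_lc_with_di_match = length(unique(pdf$lc_mz)) / nrow(lc_merged),
    fraction_di_with_lc_match = length(unique(pdf$di_mz)) / length(di_mzs),
    isomer_multiplicity = hist_tab,
    pairs = pdf,
    tol_ppm = tol_ppm
  ), class = "crossmatch_report")
}

#' @export
print.crossmatch_report <- function(x, ...) {
  cat(sprintf(
    paste0("<crossmatch_report> %d DI masses vs %d merged LC masses ",
           "(%d raw LC features) at +/-%g ppm\n",
           "  LC with DI match: %.1f%%; DI with LC match: %.1f%%\n"),
    x$n_di_features, x$n_lc_merged_masses, x$n_lc_features, x$tol_ppm,
    100 * x$fraction_lc_with_di_match, 100 * x$fraction_di_with_lc_match))
  invisible(x)
}
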
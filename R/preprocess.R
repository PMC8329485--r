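#' Keep features observed in at least k samples
#'
#' @param fm A [feature_matrix()].
#' @param k Minimum number of samples with nonzero intensity (DI default 5).
#' @return Filtered [feature_matrix()]; column order preserved.
#' @export
filter_min_occurrence <- function(fm, k = 5) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (k < 1) stop("`k` must be >= 1")
  if (k > nrow(fm$intensity)) stop("`k` exceeds the number of samples")
  occ <- colSums(fm$intensity > 0)
  keep <- occ >= k
  message("filter_min_occurrence: ", ncol(fm$intensity), " -> ", sum(keep),
          " features (k = ", k, ")")
  fm_subset_features(fm, keep)
}

#' Keep features occurring in a minimum fraction of some class
#'
#' A feature is retained if there is at least one starch-source class in which
#' it is nonzero in at least `ceiling(fraction * class size)` samples ("at
#' least 33%" read as a lower bound, so the ceiling is used at the boundary).
#' QC samples are ignored for the class counts.
#'
#' @param fm A [feature_matrix()].
#' @param metadata Metadata data frame (see [read_metadata()]) covering every
#'   row of `fm`.
#' @param fraction Required within-class occurrence fraction (LC default 1/3).
#' @return Filtered [feature_matrix()].
#' @export
filter_class_occurrence <- function(fm, metadata, fraction = 1 / 3) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  ids <- rownames(fm$intensity)
  m <- metadata[match(ids, metadata$sample_id), ]
  if (anyNA(m$sample_id)) stop("metadata missing for some samples")
  cls <- m$starch_class[!m$is_qc]
  if (anyNA(cls) || any(cls == "")) stop("unknown (empty) class label")
  x <- fm$intensity[!m$is_qc, , drop = FALSE]
  keep <- rep(FALSE, ncol(x))
  for (cl in unique(cls)) {
    sub <- x[cls == cl, , drop = FALSE]
    need <- ceiling(fraction * nrow(sub))
    keep <- keep | colSums(sub > 0) >= need
  }
  message("filter_class_occurrence: ", ncol(x), " -> ", sum(keep),
          " features (fraction = ", signif(fraction, 3), ")")
  fm_subset_features(fm, keep)
}

#' LOWESS drift correction anchored on pooled QC injections
#'
#' For each feature, a locally weighted regression of QC intensity against
#' injection order is fitted; every sample's intensity is divided by the curve
#' interpolated at its injection order and multiplied by the feature's median
#' QC intensity, so corrected intensities stay on the original physical scale.
#' Features missing (zero) in at least half of the QCs pass through unchanged
#' (logged).
#'
#' @param fm A [feature_matrix()].
#' @param metadata Metadata with `injection_order` and `is_qc`.
#' @param span LOWESS smoother span in (0, 1].
#' @return Drift-corrected [feature_matrix()].
#' @export
lowess_qc_normalize <- function(fm, metadata, span = 0.5) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (span <= 0 || span > 1) stop("`span` must be in (0, 1]")
  ids <- rownames(fm$intensity)
  m <- metadata[match(ids, metadata$sample_id), ]
  if (anyNA(m$injection_order)) stop("every sample needs an injection_order")
  if (anyDuplicated(m$injection_order)) stop("duplicate injection_order")
  qc <- which(m$is_qc)
  if (length(qc) < 4) stop("need at least 4 QC injections")
  x <- fm$intensity
  ord <- m$injection_order
  n_skipped <- 0L
  for (j in seq_len(ncol(x))) {
    qi <- x[qc, j]
    if (sum(qi > 0) < length(qc) / 2) { n_skipped <- n_skipped + 1L; next }
    use <- qi > 0
    fit <- stats::lowess(ord[qc][use], qi[use], f = span)
    curve <- stats::approx(fit$x, fit$y, xout = ord, rule = 2)$y
    curve[curve <= 0] <- NA  # degenerate fit: leave those samples untouched
    scale_back <- stats::median(qi[use])
    corr <- x[, j] / curve * scale_back
    x[, j] <- ifelse(is.na(corr), x[, j], corr)
  }
  if (n_skipped > 0) {
    message("lowess_qc_normalize: ", n_skipped,
            " feature(s) absent in >= half the QCs passed through unchanged")
  }
  feature_matrix(x, mz = fm$mz, rt = fm$rt, feature_ids = fm$feature_ids)
}

#' Scale and transform a zero-filled feature matrix for modelling
#'
#' Applies, in order: optional per-sample total-intensity normalization,
#' optional `log10(x + offset)` with offset equal to the smallest nonzero
#' value, always mean-centering, and column scaling (`"pareto"`, the default:
#' divide by the square root of the column SD; `"unit_variance"`: divide by
#' the SD; `"none"`). Constant columns are dropped (logged).
#'
#' @param fm A [feature_matrix()] or plain numeric matrix.
#' @param scaling One of `"unit_variance"`, `"pareto"`, `"none"`.
#' @param transform `"none"` or `"log10_offset"`.
#' @param normalization `"none"` or `"total_intensity"`.
#' @return Numeric matrix (samples x retained features) with attributes
#'   `center`, `scale`, `kept` (column indices retained).
#' @export
scale_transform <- function(fm, scaling = c("pareto", "unit_variance", "none"),
                            transform = c("none", "log10_offset"),
                            normalization = c("none", "total_intensity")) {
  scaling <- match.arg(scaling)
  transform <- match.arg(transform)
  normalization <- match.arg(normalization)
  x <- if (inherits(fm, "feature_matrix")) fm$intensity else as.matrix(fm)
  if (length(x) == 0) stop("empty matrix")
  if (normalization == "total_intensity") {
    tot <- rowSums(x)
    if (any(tot <= 0)) stop("sample with zero total intensity")
    x <- x / tot * mean(tot)
  }
  if (transform == "log10_offset") {
    nz <- x[x > 0]
    if (!length(nz)) stop("all-zero matrix cannot be log-transformed")
    x <- log10(x + min(nz))
  }
  sds <- apply(x, 2, stats::sd)
  kept <- which(sds > 0)
  if (length(kept) < ncol(x)) {
    message("scale_transform: dropping ", ncol(x) - length(kept),
            " constant column(s)")
  }
  x <- x[, kept, drop = FALSE]
  ctr <- colMeans(x)
  x <- sweep(x, 2, ctr)
  scl <- switch(scaling,
                unit_variance = sds[kept],
                pareto = sqrt(sds[kept]),
                none = rep(1, length(kept)))
  x <- sweep(x, 2, scl, "/")
  attr(x, "center") <- ctr
  attr(x, "scale") <- scl
  attr(x, "kept") <- kept
  x
}
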
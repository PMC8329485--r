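#' Centroided peak list
#'
#' Container for one sample's centroided mass spectrum: sorted m/z and
#' non-negative intensities.
#'
#' @param mz Numeric vector of m/z values.
#' @param intensity Numeric vector of intensities (same length, >= 0).
#' @param sample_id Sample identifier.
#' @param polarity `"negative"` or `"positive"`.
#' @return Object of class `"peaklist"`.
#' @export
peaklist <- function(mz, intensity, sample_id, polarity = "negative") {
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (any(intensity < 0)) stop("negative intensities")
  polarity <- match.arg(polarity, c("negative", "positive"))
  o <- order(mz)
  structure(list(sample_id = as.character(sample_id),
                 peaks = data.frame(mz = mz[o], intensity = intensity[o]),
                 polarity = polarity),
            class = "peaklist")
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("<peaklist> %s: %d peaks, m/z %.4f-%.4f, %s mode\n",
              x$sample_id, nrow(x$peaks),
              min(x$peaks$mz), max(x$peaks$mz), x$polarity))
  invisible(x)
}

#' Samples-by-features intensity matrix
#'
#' Aligned feature matrix: rows are samples, columns are features with a
#' consensus m/z (and optionally a retention time). Absent features are
#' zero-filled.
#'
#' @param intensity Numeric matrix, samples x features, rownames = sample ids.
#' @param mz Numeric vector of consensus m/z, one per column, strictly
#'   increasing.
#' @param rt Optional numeric vector of retention times (min), one per column.
#' @param feature_ids Optional character feature ids (default `"F00001"`...).
#' @return Object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(intensity, mz, rt = NULL, feature_ids = NULL) {
  if (!is.matrix(intensity)) stop("`intensity` must be a matrix")
  if (length(mz) != ncol(intensity)) stop("`mz` length must equal ncol(intensity)")
  if (is.unsorted(mz, strictly = TRUE)) {
    o <- order(mz)
    if (anyDuplicated(mz)) stop("consensus m/z values must be distinct")
    intensity <- intensity[, o, drop = FALSE]
    mz <- mz[o]
    if (!is.null(rt)) rt <- rt[o]
    if (!is.null(feature_ids)) feature_ids <- feature_ids[o]
  }
  if (is.null(feature_ids)) {
    feature_ids <- sprintf("F%05d", seq_along(mz))
  }
  colnames(intensity) <- feature_ids
  structure(list(intensity = intensity, mz = mz, rt = rt,
                 feature_ids = feature_ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features, m/z %.4f-%.4f%s\n",
              nrow(x$intensity), ncol(x$intensity), min(x$mz), max(x$mz),
              if (is.null(x$rt)) "" else ", with RT"))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensity)

# replace the intensity table, keeping/reindexing feature metadata
fm_subset_features <- function(fm, keep) {
  feature_matrix(fm$intensity[, keep, drop = FALSE], mz = fm$mz[keep],
                 rt = if (is.null(fm$rt)) NULL else fm$rt[keep],
                 feature_ids = fm$feature_ids[keep])
}

#' MS2 fragment spectrum
#'
#' @param feature_id Identifier linking the spectrum to a feature.
#' @param precursor_mz Precursor ion m/z.
#' @param mz,intensity Fragment m/z and intensities.
#' @return Object of class `"ms2spectrum"` with fragments sorted by m/z.
#' @export
ms2spectrum <- function(feature_id, precursor_mz, mz, intensity) {
  if (length(mz) != length(intensity)) stop("fragment mz/intensity lengths differ")
  if (any(intensity < 0)) stop("negative fragment intensities")
  if (any(mz >= precursor_mz + 0.5)) stop("fragment m/z above precursor + 0.5 Da")
  o <- order(mz)
  structure(list(feature_id = as.character(feature_id),
                 precursor_mz = precursor_mz,
                 fragments = data.frame(mz = mz[o], intensity = intensity[o])),
            class = "ms2spectrum")
}

#' @export
print.ms2spectrum <- function(x, ...) {
  cat(sprintf("<ms2spectrum> %s: precursor %.4f, %d fragments\n",
              x$feature_id, x$precursor_mz, nrow(x$fragments)))
  invisible(x)
}
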
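#' Per-feature loading scores toward a class
#'
#' Computes the direction from the overall centroid to a class centroid in
#' predictive score space (normalized) and projects every feature's predictive
#' loading vector onto it, giving a signed per-feature score of how strongly
#' the feature pulls samples toward that class. Passing several labels scores
#' the merged pseudo-class (e.g. `c("corn", "rice")` for features shared by
#' corn and rice beers).
#'
#' @param model A fitted [oplsda()] model.
#' @param class_label One or more class labels from the model.
#' @return Named numeric vector of signed scores, one per feature.
#' @export
class_loading_scores <- function(model, class_label) {
  stopifnot(inherits(model, "oplsda"))
  unknown <- setdiff(class_label, model$classes)
  if (length(unknown)) stop("unknown class: ", paste(unknown, collapse = ", "))
  sel <- model$y %in% class_label
  cen <- colMeans(model$scores[sel, , drop = FALSE])
  d <- cen - colMeans(model$scores)
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("class centroid coincides with the overall centroid")
  d <- d / nrm
  s <- drop(model$loadings %*% d)
  names(s) <- colnames(model$x)
  s
}

#' Extract the top-percentile marker set
#'
#' Thresholds the per-feature scores at the empirical percentile (the linear
#' interpolation definition, `quantile(..., type = 7)`) and keeps features
#' strictly above it. Ties at the threshold are excluded (logged), which for N
#' distinct scores selects exactly `floor(N * (100 - percentile) / 100)`
#' features.
#'
#' @param scores Named numeric vector from [class_loading_scores()].
#' @param percentile Percentile cut in (0, 100), default 95.
#' @param class_label Optional label stored with the result.
#' @return Object of class `"marker_set"`: data frame of `feature_id` and
#'   `score` (descending), with attributes `threshold`, `percentile`,
#'   `class_label`.
#' @export
extract_top_percentile <- function(scores, percentile = 95,
                                   class_label = NA_character_) {
  if (percentile <= 0 || percentile >= 100) stop("`percentile` must be in (0, 100)")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(unique(scores)) == 1) {
    warning("all scores equal; returning an empty marker set")
    thr <- scores[1]
    sel <- logical(length(scores))
  } else {
    thr <- as.numeric(stats::quantile(scores, percentile / 100, type = 7))
    sel <- scores > thr
    n_ties <- sum(scores == thr)
    if (n_ties > 1) {
      message("extract_top_percentile: ", n_ties,
              " score(s) tied at the threshold were excluded")
    }
  }
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  df <- data.frame(feature_id = ids[sel], score = unname(scores[sel]))
  df <- df[order(-df$score), ]
  rownames(df) <- NULL
  structure(df, class = c("marker_set", "data.frame"),
            threshold = thr, percentile = percentile,
            class_label = class_label)
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set>%s %d features above the %gth percentile (threshold %.4g)\n",
              if (is.na(attr(x, "class_label"))) "" else
                paste0(" [", attr(x, "class_label"), "]"),
              nrow(x), attr(x, "percentile"), attr(x, "threshold")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Van Krevelen coordinates for a set of formulas
#'
#' @param formulas Formula strings, count matrix, or named vector.
#' @param intensities Optional mean intensities (bubble sizes); coordinates
#'   are independent of them.
#' @return Data frame: `formula`, `oc_ratio`, `hc_ratio`, `element_class`,
#'   `mean_intensity`.
#' @export
van_krevelen <- function(formulas, intensities = NULL) {
  counts <- as_formula_matrix(formulas)
  if (any(counts[, "C"] < 1)) stop("every formula needs at least one carbon")
  data.frame(
    formula = formula_string(counts),
    oc_ratio = counts[, "O"] / counts[, "C"],
    hc_ratio = counts[, "H"] / counts[, "C"],
    element_class = element_class(counts),
    mean_intensity = if (is.null(intensities)) NA_real_ else intensities,
    row.names = NULL
  )
}

#' Van Krevelen diagram
#'
#' H/C against O/C scatter with the conventional composition-class colors
#' (CHO blue, CHNO orange, CHOS green, CHNOS red, P purple) and bubble sizes
#' proportional to mean intensity.
#'
#' @param vk Data frame from [van_krevelen()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_van_krevelen <- function(vk, ...) {
  pal <- c(CHO = "#1f77b4", CHNO = "#ff7f0e", CHOS = "#2ca02c",
           CHNOS = "#d62728", P = "#9467bd", other = "grey50")
  cex <- if (all(is.na(vk$mean_intensity))) 1 else {
    r <- vk$mean_intensity / max(vk$mean_intensity, na.rm = TRUE)
    0.5 + 2 * sqrt(pmax(r, 0))
  }
  graphics::plot(vk$oc_ratio, vk$hc_ratio, pch = 19,
                 col = grDevices::adjustcolor(pal[vk$element_class], 0.7),
                 cex = cex, xlab = "O/C", ylab = "H/C",
                 xlim = c(0, max(1.2, vk$oc_ratio)),
                 ylim = c(0, max(2.5, vk$hc_ratio)), ...)
  graphics::legend("bottomright", legend = names(pal), col = pal, pch = 19,
                   cex = 0.8)
  invisible(vk)
}
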
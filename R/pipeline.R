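#' Run the full starch-source authentication pipeline on a synthetic cohort
#'
#' End-to-end realization of the workflow: cohort simulation, mass alignment,
#' minimum-occurrence filtering, OPLS-DA with stratified cross-validation and
#' CV-ANOVA, per-class 95th-percentile marker extraction with ground-truth
#' recovery, formula annotation of markers, van Krevelen characterization, and
#' a mass-difference network over the annotated marker formulas. Optionally an
#' LC-ToF companion cohort is generated for QC drift correction, MS2
#' similarity networking, and DI/LC cross-platform matching. Identical
#' `config` and seed give a byte-identical summary.
#'
#' @param config List of settings; missing entries fall back to defaults:
#'   `cohort` (arguments to [cohort_config()]), `align_tol_ppm` (0.5),
#'   `min_occurrence` (5), `n_predictive` (3), `n_orthogonal` (1),
#'   `folds` (7), `percentile` (95), `with_lc` (FALSE), `holdout_fraction`
#'   (0, no held-out evaluation).
#' @param out_dir Optional directory; when given, the summary JSON, marker
#'   CSVs, and network GraphML files are written there.
#' @return List with the fitted `model`, `cv`, `markers` (per class),
#'   `recovery`, `mdin`, and a flat `summary` list (also serialized to JSON
#'   when `out_dir` is given).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(
    cohort = list(), align_tol_ppm = 0.5, min_occurrence = 5,
    n_predictive = 3, n_orthogonal = 1, folds = 7, percentile = 95,
    with_lc = FALSE, holdout_fraction = 0
  ), config)
  cc <- do.call(cohort_config, cfg$cohort)
  catalog <- builtin_marker_catalog()
  cohort <- generate_cohort(cc, catalog)

  fm <- align_masses(cohort$peaklists, tol_ppm = cfg$align_tol_ppm)
  fm <- filter_min_occurrence(fm, cfg$min_occurrence)
  truth <- match_ground_truth(fm, cohort$truth, tol_ppm = cfg$align_tol_ppm)

  md <- cohort$metadata
  y <- factor(md$starch_class[match(rownames(fm$intensity), md$sample_id)])
  x <- fm$intensity

  holdout <- integer(0)
  if (cfg$holdout_fraction > 0) {
    with_seed(cc$seed + 1L, {
      for (cl in levels(y)) {
        idx <- which(y == cl)
        holdout <- c(holdout, sample(idx, round(cfg$holdout_fraction * length(idx))))
      }
    })
  }
  train <- setdiff(seq_along(y), holdout)

  model <- oplsda(x[train, , drop = FALSE], y[train],
                  n_predictive = cfg$n_predictive,
                  n_orthogonal = cfg$n_orthogonal)
  cv <- cross_validate(x[train, , drop = FALSE], y[train],
                       n_predictive = cfg$n_predictive,
                       n_orthogonal = cfg$n_orthogonal,
                       folds = cfg$folds, seed = cc$seed)
  anova <- cv_anova(cv)

  holdout_accuracy <- NA_real_
  if (length(holdout)) {
    pr <- predict(model, x[holdout, , drop = FALSE])
    holdout_accuracy <- mean(pr$class == y[holdout])
  }

  marker_classes <- list(wheat = "wheat", corn = "corn", rice = "rice",
                         corn_and_rice = c("corn", "rice"))
  markers <- list(); recovery <- list()
  for (nm in names(marker_classes)) {
    sc <- class_loading_scores(model, marker_classes[[nm]])
    ms <- extract_top_percentile(sc, cfg$percentile, class_label = nm)
    markers[[nm]] <- ms
    planted <- truth$feature_id[truth$marker_class == nm]
    planted <- planted[!is.na(planted)]
    recovery[[nm]] <- if (length(planted))
      mean(planted %in% ms$feature_id) else NA_real_
  }

  # annotate marker masses and build the MDiN over assigned formulas
  marker_ids <- unique(unlist(lapply(markers, function(m) m$feature_id)))
  marker_mz <- fm$mz[match(marker_ids, fm$feature_ids)]
  ann <- lapply(marker_mz, enumerate_formulas, adducts = "[M-H]-",
                tol_ppm = max(0.5, 5 * cc$mass_error_ppm_sd))
  assigned <- !vapply(ann, function(a) is.null(a$assigned), logical(1))
  formulas <- vapply(ann[assigned], function(a) a$assigned$formula, character(1))
  vk <- van_krevelen(unique(formulas))
  net <- build_mdin(stats::setNames(unique(formulas), unique(formulas)))

  summary <- list(
    n_samples = length(y), n_features_aligned = ncol(x),
    r2y = model$r2y, q2 = cv$q2, cv_anova_p = anova$p,
    cv_accuracy = cv$accuracy, holdout_accuracy = holdout_accuracy,
    marker_counts = lapply(markers, nrow),
    marker_recovery = recovery,
    n_markers_annotated = sum(assigned),
    mdin_nodes = igraph::vcount(net), mdin_edges = igraph::ecount(net)
  )

  lc <- NULL
  if (isTRUE(cfg$with_lc)) {
    # same seed: the LC platform re-measures the same underlying chemistry
    lc_cfg <- utils::modifyList(
      as.list(cc)[setdiff(names(cc), "mode")],
      list(mode = "lc_tof", mass_error_ppm_sd = 3,
           drift_slope = if (cc$drift_slope != 0) cc$drift_slope else 0.002))
    lc_cc <- do.call(cohort_config, lc_cfg)
    lc_cohort <- generate_cohort(lc_cc, catalog)
    lc_fm <- lowess_qc_normalize(lc_cohort$features, lc_cohort$metadata)
    msnet <- build_similarity_network(lc_cohort$ms2, cutoff = 0.65)
    merged <- merge_isomers(data.frame(mz = lc_fm$mz, rt = lc_fm$rt,
                                       intensity = colMeans(lc_fm$intensity)))
    xmatch <- match_features(fm$mz, merged, tol_ppm = 5)
    lc <- list(features = lc_fm, msnet = msnet, crossmatch = xmatch)
    summary$msnet_nodes <- igraph::vcount(msnet)
    summary$msnet_edges <- igraph::ecount(msnet)
    summary$fraction_lc_with_di_match <- xmatch$fraction_lc_with_di_match
    summary$fraction_di_with_lc_match <- xmatch$fraction_di_with_lc_match
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(markers)) {
      utils::write.csv(as.data.frame(markers[[nm]]),
                       file.path(out_dir, paste0("markers_", nm, ".csv")),
                       row.names = FALSE)
    }
    write_graph_file(net, file.path(out_dir, "mdin.graphml"))
    utils::write.csv(vk, file.path(out_dir, "van_krevelen.csv"),
                     row.names = FALSE)
    if (!is.null(lc)) {
      write_graph_file(lc$msnet, file.path(out_dir, "msnet.graphml"))
    }
  }

  list(model = model, cv = cv, cv_anova = anova, feature_matrix = fm,
       truth = truth, markers = markers, recovery = recovery,
       van_krevelen = vk, mdin = net, lc = lc, summary = summary)
}
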
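#' Built-in marker catalog of starch-source-specific formulas
#'
#' Molecular formulas characteristic of the starch source used in brewing, as
#' established for the benzoxazinoid-glucoside chemistry of wheat (blepharin,
#' HMBOA/DIMBOA glucosides and their sulfates), the oxylipin/hydroxycinnamoyl
#' chemistry of corn (including the C20 lipid series and oxindoleacetic-acid
#' glucosides), the peptide-like and dioxindole chemistry of rice, and two
#' compositions shared by corn and rice. Each entry carries a base intensity
#' and a neutral-loss MS2 template used by the LC-mode generator.
#'
#' @return Object of class `"marker_catalog"`: data frame with columns
#'   `formula`, `marker_class`, `base_intensity`, and list-column
#'   `ms2_template` (data frames of `loss`, `rel_intensity`).
#' @export
builtin_marker_catalog <- function() {
  entries <- list(
    wheat = c("C14H17NO8", "C15H19NO9", "C15H21NO12S", "C14H17NO9",
              "C15H19NO10", "C15H21NO13S", "C10H9NO3", "C11H11NO3",
              "C23H31NO13", "C26H39NO20", "C26H37NO19"),
    corn = c("C10H9NO4", "C16H19NO9", "C22H29NO14", "C12H14O5", "C12H14O6",
             "C20H32O4", "C20H34O4", "C20H32O5", "C21H34O4", "C21H36O4",
             "C21H34O5"),
    rice = c("C10H9NO5", "C16H21NO11", "C22H31NO16", "C16H23NO11",
             "C22H33NO16", "C27H37N5O7", "C29H40N6O8", "C24H40N6O8",
             "C22H35N5O11"),
    corn_and_rice = c("C10H13NO7", "C16H19NO10")
  )
  df <- do.call(rbind, lapply(names(entries), function(cl) {
    data.frame(formula = entries[[cl]], marker_class = cl,
               stringsAsFactors = FALSE)
  }))
  stopifnot(!anyDuplicated(df$formula), all(chemical_filters(df$formula)))
  df$base_intensity <- 1e6
  # glucoside-rich compositions fragment dominantly by glucosyl loss; the
  # remaining (lipid-like) entries by water/CO2 losses
  counts <- parse_formula(df$formula)
  glyco <- counts[, "O"] >= 8
  tmpl_glyco <- data.frame(loss = c("C6H10O5", "H2O", "CO2"),
                           rel_intensity = c(1.0, 0.5, 0.3))
  tmpl_lipid <- data.frame(loss = c("H2O", "CO2", "CH2O"),
                           rel_intensity = c(1.0, 0.6, 0.3))
  df$ms2_template <- lapply(glyco, function(g) if (g) tmpl_glyco else tmpl_lipid)
  rownames(df) <- NULL
  structure(df, class = c("marker_catalog", "data.frame"))
}

#' Cohort generator configuration
#'
#' Defaults describe the simulated study conditions: 25 samples per starch
#' class, 2,000 background formulas, sub-ppm (0.1 ppm SD) mass error in
#' DI-FTICR mode, log-normal intensity scatter (sigma 0.5 on the log scale),
#' 8-fold marker elevation, and 10% random dropout. LC-ToF mode uses a 3 ppm
#' mass error, a linear intensity drift over injection order, and pooled QCs
#' every 10th injection.
#'
#' @param n_samples_per_class Samples per starch class.
#' @param n_background_formulas Background CHNO formulas shared by all classes.
#' @param mass_error_ppm_sd SD of the relative mass error (ppm).
#' @param intensity_lognormal_sigma SD of log intensity per measurement.
#' @param marker_fold_change Intensity fold elevation of markers in their own
#'   class (> 1).
#' @param dropout_prob Per-measurement probability a feature is not detected.
#' @param drift_slope LC mode: relative intensity drift per injection.
#' @param seed Integer seed; identical seed gives bit-identical cohorts.
#' @param mode `"di_fticr"` (peak lists) or `"lc_tof"` (feature table + MS2).
#' @return List of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples_per_class = 25,
                          n_background_formulas = 2000,
                          mass_error_ppm_sd = 0.1,
                          intensity_lognormal_sigma = 0.5,
                          marker_fold_change = 8,
                          dropout_prob = 0.1,
                          drift_slope = 0,
                          seed = 1,
                          mode = c("di_fticr", "lc_tof")) {
  mode <- match.arg(mode)
  if (marker_fold_change <= 1) stop("`marker_fold_change` must be > 1")
  if (dropout_prob < 0 || dropout_prob >= 1) stop("`dropout_prob` must be in [0, 1)")
  if (mass_error_ppm_sd < 0 || intensity_lognormal_sigma < 0) {
    stop("noise parameters must be >= 0")
  }
  if (n_samples_per_class < 1 || n_background_formulas < 1) {
    stop("sample and feature counts must be positive")
  }
  structure(list(n_samples_per_class = n_samples_per_class,
                 n_background_formulas = n_background_formulas,
                 mass_error_ppm_sd = mass_error_ppm_sd,
                 intensity_lognormal_sigma = intensity_lognormal_sigma,
                 marker_fold_change = marker_fold_change,
                 dropout_prob = dropout_prob,
                 drift_slope = drift_slope,
                 seed = seed, mode = mode),
            class = "cohort_config")
}

# uniform rejection sampling of chemically plausible CHNO formulas whose
# deprotonated ion lands in m/z 100-1000, excluding a reserved set
.sample_background <- function(n, exclude) {
  out <- character(0)
  while (length(out) < n) {
    m <- max(2000, 3 * (n - length(out)))
    cand <- cbind(C = sample(4:45, m, replace = TRUE),
                  H = sample(2:94, m, replace = TRUE),
                  N = sample(0:4, m, replace = TRUE),
                  O = sample(0:20, m, replace = TRUE),
                  S = 0L, P = 0L, Cl = 0L)
    ok <- chemical_filters(cand)
    mz <- drop(cand %*% ELEMENT_MASSES[colnames(cand)]) + adduct_shifts()[["[M-H]-"]]
    ok <- ok & mz >= 100 & mz <= 1000
    fs <- formula_string(cand[ok, , drop = FALSE])
    fs <- setdiff(unique(fs), c(exclude, out))
    out <- c(out, fs)
  }
  out[seq_len(n)]
}

#' Generate a synthetic beer cohort with planted marker chemistry
#'
#' Builds a 4-class cohort (barley, wheat, corn, rice) over a shared
#' background of chemically filtered CHNO formulas plus the catalog's
#' class-specific markers. Marker intensities are elevated
#' `marker_fold_change`-fold in their own class (corn-and-rice markers in both
#' corn and rice); measured m/z values carry a relative Gaussian error;
#' intensities are log-normal with independent dropout. LC mode additionally
#' assigns retention times, applies a linear injection-order drift,
#' interleaves a pooled QC every 10th injection, and emits template-based MS2
#' spectra for the marker features.
#'
#' @param config A [cohort_config()].
#' @param catalog A [builtin_marker_catalog()]-style catalog.
#' @return List with elements
#'   `peaklists` (DI mode) or `features` (a [feature_matrix()], LC mode),
#'   `metadata` (data frame), `truth` (data frame: formula, marker_class,
#'   theoretical ion m/z, and in LC mode the feature id), and in LC mode
#'   `ms2` (list of [ms2spectrum()]).
#' @export
generate_cohort <- function(config = cohort_config(),
                            catalog = builtin_marker_catalog()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, .generate_cohort_impl(config, catalog))
}

.generate_cohort_impl <- function(config, catalog) {
  classes <- c("barley", "wheat", "corn", "rice")
  npc <- config$n_samples_per_class
  n_samp <- npc * length(classes)
  sample_class <- rep(classes, each = npc)
  sample_ids <- sprintf("S%03d", seq_len(n_samp))

  bg <- .sample_background(config$n_background_formulas, catalog$formula)
  formulas <- c(bg, catalog$formula)
  n_feat <- length(formulas)
  theo_mz <- ion_mz(formulas, "[M-H]-")
  is_marker <- c(rep(FALSE, length(bg)), rep(TRUE, nrow(catalog)))
  marker_class <- c(rep(NA_character_, length(bg)), catalog$marker_class)

  base <- exp(stats::rnorm(n_feat, log(1e6), 1))
  base[is_marker] <- catalog$base_intensity

  # expected intensity per sample x feature, before measurement noise
  fold <- matrix(1, n_samp, n_feat)
  for (j in which(is_marker)) {
    cl <- marker_class[j]
    elevated <- if (cl == "corn_and_rice") sample_class %in% c("corn", "rice")
                else sample_class == cl
    fold[elevated, j] <- config$marker_fold_change
  }
  expected <- sweep(fold, 2, base, "*")

  noise <- matrix(exp(stats::rnorm(n_samp * n_feat, 0,
                                   config$intensity_lognormal_sigma)),
                  n_samp, n_feat)
  intensity <- expected * noise
  detected <- matrix(stats::runif(n_samp * n_feat) >= config$dropout_prob,
                     n_samp, n_feat)

  truth <- data.frame(formula = catalog$formula,
                      marker_class = catalog$marker_class,
                      ion_mz = theo_mz[is_marker],
                      row.names = NULL)

  if (config$mode == "di_fticr") {
    mz_err <- matrix(stats::rnorm(n_samp * n_feat, 0,
                                  config$mass_error_ppm_sd * 1e-6),
                     n_samp, n_feat)
    metadata <- data.frame(sample_id = sample_ids, starch_class = sample_class,
                           injection_order = seq_len(n_samp), is_qc = FALSE)
    peaklists <- lapply(seq_len(n_samp), function(i) {
      keep <- detected[i, ]
      peaklist(theo_mz[keep] * (1 + mz_err[i, keep]),
               intensity[i, keep], sample_id = sample_ids[i])
    })
    return(list(peaklists = peaklists, metadata = metadata, truth = truth))
  }

  # ---- LC-ToF mode ----
  run_order <- sample.int(n_samp)          # randomized injection sequence
  n_qc <- floor(n_samp / 9)
  n_inj <- n_samp + n_qc
  is_qc_inj <- seq_len(n_inj) %% 10 == 0
  n_qc <- sum(is_qc_inj)
  if (n_qc < 1 && config$drift_slope != 0) {
    warning("cohort too small for QC injections; drift cannot be corrected")
  }
  inj_sample <- integer(n_inj)
  inj_sample[!is_qc_inj] <- run_order

  rt <- stats::runif(n_feat, 0.5, 9.5)
  # the feature table reports consensus m/z over the aligned injections, so
  # the per-measurement error averages down by sqrt(n)
  feat_mz <- theo_mz * (1 + stats::rnorm(n_feat, 0,
    config$mass_error_ppm_sd * 1e-6 / sqrt(n_samp)))

  pooled <- colMeans(expected)
  qc_noise <- matrix(exp(stats::rnorm(n_qc * n_feat, 0,
                                      config$intensity_lognormal_sigma / 2)),
                     n_qc, n_feat)

  x <- matrix(0, n_inj, n_feat)
  qi <- 0L
  for (inj in seq_len(n_inj)) {
    drift <- 1 + config$drift_slope * inj
    if (is_qc_inj[inj]) {
      qi <- qi + 1L
      x[inj, ] <- pooled * qc_noise[qi, ] * drift
    } else {
      s <- inj_sample[inj]
      x[inj, ] <- intensity[s, ] * detected[s, ] * drift
    }
  }
  inj_ids <- character(n_inj)
  inj_ids[is_qc_inj] <- sprintf("QC%02d", seq_len(n_qc))
  inj_ids[!is_qc_inj] <- sample_ids[inj_sample[!is_qc_inj]]
  rownames(x) <- inj_ids
  metadata <- data.frame(
    sample_id = inj_ids,
    starch_class = ifelse(is_qc_inj, NA, sample_class[replace(inj_sample, is_qc_inj, 1)]),
    injection_order = seq_len(n_inj),
    is_qc = is_qc_inj)
  o <- order(theo_mz)
  fm <- feature_matrix(x[, o, drop = FALSE], mz = feat_mz[o], rt = rt[o])
  truth$feature_id <- fm$feature_ids[match(which(is_marker), o)]

  ms2_seeds <- sample.int(.Machine$integer.max %/% 2, nrow(truth))
  cat_idx <- match(truth$formula, catalog$formula)
  ms2 <- lapply(seq_len(nrow(truth)), function(k) {
    s <- simulate_ms2(catalog[cat_idx[k], ], seed = ms2_seeds[k])
    s$feature_id <- truth$feature_id[k]
    s
  })
  list(features = fm, metadata = metadata, truth = truth, ms2 = ms2)
}

#' Simulate an MS2 spectrum from a marker's neutral-loss template
#'
#' Fragments are placed at the precursor m/z minus each template loss mass,
#' with the template's relative intensities (base peak 1000). Between 5 and 15
#' uniform noise peaks at no more than 2% of the base intensity are added.
#' Deterministic under `seed`.
#'
#' @param entry One catalog row (data frame with `formula` and list-column
#'   `ms2_template`), or a list with those fields.
#' @param seed Integer seed.
#' @return An [ms2spectrum()] named after the formula.
#' @export
simulate_ms2 <- function(entry, seed = 1) {
  tmpl <- entry$ms2_template
  if (is.list(tmpl) && !is.data.frame(tmpl)) tmpl <- tmpl[[1]]
  if (is.null(tmpl) || nrow(tmpl) == 0) stop("empty MS2 template")
  formula <- if (is.data.frame(entry)) entry$formula[[1]] else entry$formula
  prec <- unname(ion_mz(formula, "[M-H]-"))
  frag_mz <- prec - formula_mass(tmpl$loss)
  if (any(frag_mz <= 0)) stop("template loss exceeds precursor mass")
  frag_int <- tmpl$rel_intensity * 1000
  with_seed(seed, {
    n_noise <- sample(5:15, 1)
    noise_mz <- stats::runif(n_noise, 50, prec - 1)
    noise_int <- stats::runif(n_noise, 0, 0.02 * max(frag_int))
    ms2spectrum(formula, prec, c(frag_mz, noise_mz), c(frag_int, noise_int))
  })
}

#' Locate planted marker features in an aligned feature matrix
#'
#' Matches the ground-truth theoretical marker masses against the consensus
#' m/z values of a feature matrix within a ppm tolerance (nearest feature
#' wins).
#'
#' @param fm A [feature_matrix()].
#' @param truth Ground-truth data frame from [generate_cohort()].
#' @param tol_ppm Match tolerance in ppm.
#' @return `truth` with an added `feature_id` column (`NA` where unmatched).
#' @export
match_ground_truth <- function(fm, truth, tol_ppm = 1) {
  idx <- vapply(truth$ion_mz, function(m) {
    i <- which.min(abs(fm$mz - m))
    if (abs(fm$mz[i] - m) / m * 1e6 <= tol_ppm) i else NA_integer_
  }, integer(1))
  truth$feature_id <- ifelse(is.na(idx), NA_character_, fm$feature_ids[idx])
  truth
}
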
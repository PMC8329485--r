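test_that("the marker catalog carries the expected class chemistry", {
  cat <- builtin_marker_catalog()
  expect_true(all(c("C20H32O4", "C10H9NO4") %in%
                    cat$formula[cat$marker_class == "corn"]))
  expect_true("C14H17NO8" %in% cat$formula[cat$marker_class == "wheat"])
  expect_true("C10H9NO5" %in% cat$formula[cat$marker_class == "rice"])
  expect_true(all(c("C10H13NO7", "C16H19NO10") %in%
                    cat$formula[cat$marker_class == "corn_and_rice"]))
  expect_false(anyDuplicated(cat$formula) > 0)
  expect_true(all(chemical_filters(cat$formula)))
  expect_true(all(vapply(cat$ms2_template, nrow, integer(1)) > 0))
})

test_that("cohort generation is bit-identical under a fixed seed", {
  c1 <- small_cohort(seed = 7, npc = 4, nbg = 80)
  c2 <- small_cohort(seed = 7, npc = 4, nbg = 80)
  expect_identical(c1$peaklists, c2$peaklists)
  expect_identical(c1$truth, c2$truth)
  c3 <- small_cohort(seed = 8, npc = 4, nbg = 80)
  expect_false(identical(c1$peaklists, c3$peaklists))
  # the generator does not perturb the caller's RNG
  set.seed(1); before <- runif(3)
  invisible(small_cohort(seed = 7, npc = 2, nbg = 40))
  set.seed(1)
  expect_identical(runif(3), before)
})

test_that("the noiseless limit reproduces theoretical masses exactly", {
  ch <- small_cohort(seed = 2, npc = 3, nbg = 60, mass_error_ppm_sd = 0)
  theo <- sort(unique(unlist(lapply(ch$peaklists, function(p) p$peaks$mz))))
  # all measured masses coincide across samples (no per-measurement error)
  for (p in ch$peaklists) {
    expect_true(all(p$peaks$mz %in% theo))
  }
  expect_true(all(abs(sort(ch$truth$ion_mz) -
                        theo[match(round(sort(ch$truth$ion_mz), 5),
                                   round(theo, 5))]) < 1e-9))
})

test_that("markers are elevated in their own class across seeds", {
  for (s in 1:5) {
    ch <- generate_cohort(cohort_config(n_samples_per_class = 25,
                                        n_background_formulas = 50,
                                        marker_fold_change = 8,
                                        dropout_prob = 0.1, seed = s))
    fm <- quiet(align_masses(ch$peaklists, 0.5))
    tru <- match_ground_truth(fm, ch$truth, 0.5)
    cls <- ch$metadata$starch_class
    for (k in which(tru$marker_class == "corn")) {
      j <- match(tru$feature_id[k], fm$feature_ids)
      corn_mean <- mean(fm$intensity[cls == "corn", j])
      wheat_mean <- mean(fm$intensity[cls == "wheat", j])
      expect_gt(corn_mean, wheat_mean)
      expect_gte(corn_mean, 8 / 2 * wheat_mean / 2)
    }
    # corn_and_rice markers are high in both corn and rice
    for (k in which(tru$marker_class == "corn_and_rice")) {
      j <- match(tru$feature_id[k], fm$feature_ids)
      expect_gt(mean(fm$intensity[cls %in% c("corn", "rice"), j]),
                2 * mean(fm$intensity[cls == "barley", j]))
    }
  }
})

test_that("generator validates its configuration", {
  expect_error(cohort_config(marker_fold_change = 1), "> 1")
  expect_error(cohort_config(dropout_prob = 1.2), "dropout")
  expect_error(cohort_config(mass_error_ppm_sd = -1), ">= 0")
  expect_error(cohort_config(n_samples_per_class = 0), "positive")
})

test_that("LC cohorts carry QCs every 10th injection with bounded CV", {
  ch <- generate_cohort(cohort_config(n_samples_per_class = 15,
                                      n_background_formulas = 100,
                                      drift_slope = 0, seed = 11,
                                      mode = "lc_tof"))
  md <- ch$metadata
  expect_true(all(md$injection_order[md$is_qc] %% 10 == 0))
  expect_equal(sum(md$is_qc), floor(60 / 9))
  # QC CV <= sigma when there is no drift (QCs are pooled means)
  qc_rows <- match(md$sample_id[md$is_qc], rownames(ch$features$intensity))
  cvs <- apply(ch$features$intensity[qc_rows, ], 2,
               function(v) sd(v) / mean(v))
  expect_lte(median(cvs), 0.5)
  expect_true(!is.null(ch$features$rt))
  expect_true(all(ch$features$rt >= 0.5 & ch$features$rt <= 9.5))
  expect_length(ch$ms2, nrow(ch$truth))
})

test_that("simulated MS2 spectra honor their templates and noise bounds", {
  cat <- builtin_marker_catalog()
  entry <- cat[cat$formula == "C16H19NO9", ]
  sp <- simulate_ms2(entry, seed = 5)
  prec <- unname(ion_mz("C16H19NO9", "[M-H]-"))
  expect_equal(sp$precursor_mz, prec, tolerance = 1e-9)
  # glucosyl loss fragment present
  expect_true(any(abs(sp$fragments$mz - (prec - 162.05282)) < 1e-4))
  # determinism
  expect_identical(simulate_ms2(entry, seed = 5), sp)
  expect_false(identical(simulate_ms2(entry, seed = 6), sp))
  # noise peaks at <= 2% of base
  base <- max(sp$fragments$intensity)
  tmpl_n <- nrow(entry$ms2_template[[1]])
  noise <- sort(sp$fragments$intensity, decreasing = TRUE)[-seq_len(tmpl_n)]
  expect_true(all(noise <= 0.02 * base + 1e-12))
  expect_gte(length(noise), 5); expect_lte(length(noise), 15)
  bad <- entry; bad$ms2_template <- list(data.frame())
  expect_error(simulate_ms2(bad, 1), "empty")
})
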
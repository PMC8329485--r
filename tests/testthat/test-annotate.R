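test_that("enumeration recovers printed and derived formula-mass pairs", {
  a <- enumerate_formulas(335.22278, "[M-H]-", tol_ppm = 0.5)
  expect_false(is.null(a$assigned))
  expect_equal(a$assigned$formula, "C20H32O4")
  expect_equal(a$provenance, "enumeration")
  # glucose from its deprotonated mass
  g <- enumerate_formulas(179.05611, "[M-H]-", tol_ppm = 1)
  expect_true("C6H12O6" %in% g$candidates$formula)
  # below any valid formula mass
  expect_equal(nrow(enumerate_formulas(1.0, "[M-H]-", 1)$candidates), 0)
  expect_error(enumerate_formulas(300, tol_ppm = 0), "tol_ppm")
})

test_that("enumeration agrees with the library-lookup oracle", {
  oracle <- make_enumeration_oracle(520)
  set.seed(42)
  mzs <- runif(100, 100, 500)
  for (mz in mzs) {
    for (ad in c("[M-H]-", "[M+Cl]-")) {
      expected <- sort(oracle(mz, ad, 1))
      got <- enumerate_formulas(mz, ad, tol_ppm = 1)
      got <- sort(got$candidates$formula[got$candidates$adduct == ad])
      expect_identical(got, expected)
    }
  }
})

test_that("assigned formulas are self-consistent with their measured mass", {
  set.seed(7)
  mzs <- c(runif(30, 100, 500),
           ion_mz(builtin_marker_catalog()$formula, "[M-H]-"))
  for (mz in mzs) {
    a <- enumerate_formulas(mz, tol_ppm = 1)
    if (is.null(a$assigned)) next
    back <- ion_mz(a$assigned$formula, a$assigned$adduct)
    expect_lt(abs(back - mz) / mz * 1e6, 1)
  }
})

test_that("ambiguity rule assigns only unique-or-3x-better candidates", {
  set.seed(11)
  mzs <- runif(200, 400, 900)
  checked <- 0
  for (mz in mzs) {
    a <- enumerate_formulas(mz, "[M-H]-", tol_ppm = 5)
    if (nrow(a$candidates) < 2) next
    checked <- checked + 1
    e <- abs(a$candidates$error_ppm)
    if (is.null(a$assigned)) {
      expect_gt(e[1] * 3, e[2])
    } else {
      expect_lte(e[1] * 3, e[2])
      expect_equal(a$assigned$formula, a$candidates$formula[1])
    }
  }
  expect_gt(checked, 10)  # the property was actually exercised
})

test_that("alignment clusters by ppm gaps and splits wide clusters", {
  p1 <- peaklist(c(100.1, 200.2, 500.0), c(5, 3, 1), "a")
  p2 <- peaklist(c(100.1, 200.2, 500.0), c(2, 4, 6), "b")
  fm <- align_masses(list(p1, p2), tol_ppm = 1)
  expect_equal(dim(fm$intensity), c(2L, 3L))
  expect_true(all(fm$intensity > 0))
  # 2 ppm apart at 1 ppm tolerance: two features
  q1 <- peaklist(c(500.00000), 1, "a")
  q2 <- peaklist(c(500.00100), 1, "b")
  fm2 <- align_masses(list(q1, q2), tol_ppm = 1)
  expect_equal(ncol(fm2$intensity), 2L)
  # within tolerance: one feature, intensity-weighted consensus
  r2 <- peaklist(c(500.00020), 3, "b")
  fm3 <- align_masses(list(q1, r2), tol_ppm = 1)
  expect_equal(ncol(fm3$intensity), 1L)
  expect_equal(fm3$mz, (500.0 * 1 + 500.0002 * 3) / 4, tolerance = 1e-9)
})

test_that("a chain of close peaks is split, never silently merged", {
  # 11 peaks, each 2 ppm from the previous: chains under single linkage at
  # 3 ppm, total span 20 ppm > 3 * tol
  mz <- 500 * cumprod(c(1, rep(1 + 2e-6, 10)))
  pls <- lapply(seq_along(mz), function(i)
    peaklist(mz[i], 1, paste0("s", i)))
  expect_message(fm <- align_masses(pls, tol_ppm = 3), "splitting")
  spans <- vapply(seq_along(fm$mz), function(j) {
    hit <- fm$intensity[, j] > 0
    v <- mz[hit]
    (max(v) - min(v)) / mean(v) * 1e6
  }, numeric(1))
  expect_true(all(spans <= 9 + 1e-6))
})

test_that("noiseless cohort alignment recovers exactly the planted masses", {
  ch <- small_cohort(seed = 3, npc = 5, nbg = 150, mass_error_ppm_sd = 0,
                     dropout_prob = 0)
  fm <- quiet(align_masses(ch$peaklists, tol_ppm = 0.5))
  # with zero mass error and zero dropout every sample carries every feature
  # at its exact theoretical ion m/z
  expect_equal(ncol(fm$intensity), 150 + nrow(builtin_marker_catalog()))
  expect_true(all(fm$intensity > 0))
  for (i in c(1, 10)) {
    pk <- ch$peaklists[[i]]$peaks$mz
    expect_equal(sort(pk), sort(fm$mz), tolerance = 1e-12)
  }
  # marker masses sit exactly on their features
  expect_true(all(vapply(ch$truth$ion_mz, function(m) min(abs(fm$mz - m)),
                         numeric(1)) < 1e-9))
})

test_that("network annotation propagates along library differences", {
  lib <- builtin_reaction_library()
  # methoxylation link: blepharin -> HMBOA-glucoside
  mzs <- ion_mz(c("C14H17NO8", "C15H19NO9"), "[M-H]-")
  res <- network_annotation(mzs, data.frame(mz = mzs[1], formula = "C14H17NO8"),
                            lib, tol_ppm = 1)
  expect_equal(res[[2]]$assigned$formula, "C15H19NO9")
  expect_equal(res[[2]]$provenance, "network")
  expect_equal(res[[1]]$provenance, "seed")

  # two successive hydrogenations need two propagation rounds
  chain <- ion_mz(c("C20H30O4", "C20H32O4", "C20H34O4"), "[M-H]-")
  res2 <- network_annotation(chain,
                             data.frame(mz = chain[1], formula = "C20H30O4"),
                             lib, tol_ppm = 1)
  expect_equal(res2[[3]]$assigned$formula, "C20H34O4")

  # no pair within tolerance: only the seed is assigned
  far <- c(ion_mz("C14H17NO8", "[M-H]-"), 700.123456)
  res3 <- network_annotation(far, data.frame(mz = far[1], formula = "C14H17NO8"),
                             lib, tol_ppm = 1)
  expect_null(res3[[2]]$assigned)
  expect_error(network_annotation(far, data.frame(mz = far[1],
                                                  formula = "C14H17NO8"),
                                  lib[0, ], 1), "empty")
})

test_that("propagated annotations never drift from the measured mass", {
  ch <- small_cohort(seed = 5, npc = 4, nbg = 80, mass_error_ppm_sd = 0.1)
  fm <- quiet(align_masses(ch$peaklists, 0.5))
  seeds <- data.frame(mz = ch$truth$ion_mz[1], formula = ch$truth$formula[1])
  res <- network_annotation(fm$mz, seeds, tol_ppm = 1)
  for (a in res) {
    if (is.null(a$assigned)) next
    expect_lt(abs(ion_mz(a$assigned$formula) - a$mz) / a$mz * 1e6, 1)
  }
})
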
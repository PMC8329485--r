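make_fm <- function(x, mz = NULL) {
  if (is.null(mz)) mz <- 100 + seq_len(ncol(x))
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  feature_matrix(x, mz = mz)
}

test_that("minimum-occurrence filter keeps features seen in >= k samples", {
  # 10 samples x 6 features with occupancies 1..6
  x <- matrix(0, 10, 6)
  for (j in 1:6) x[seq_len(j), j] <- 1
  fm <- make_fm(x)
  out <- quiet(filter_min_occurrence(fm, 3))
  expect_equal(ncol(out$intensity), 4)
  expect_equal(out$mz, fm$mz[3:6])  # order preserved
  # all-zero feature removed at any k; feature in 4 samples dies at k = 5
  expect_equal(ncol(quiet(filter_min_occurrence(make_fm(cbind(x, 0)), 1))$intensity), 6)
  expect_equal(sum(quiet(filter_min_occurrence(fm, 5))$mz %in% fm$mz[4]), 0)
  expect_error(filter_min_occurrence(fm, 11), "exceeds")
  # idempotent
  expect_equal(quiet(filter_min_occurrence(out, 3))$intensity, out$intensity)
})

test_that("class-occurrence filter uses the ceiling of the class fraction", {
  md <- data.frame(sample_id = paste0("S", 1:22),
                   starch_class = rep(c("corn", "wheat"), c(12, 10)),
                   is_qc = FALSE)
  x <- matrix(0, 22, 3)
  x[1:4, 1] <- 1            # 4/12 corn = 33.3% -> ceil(4) = 4: kept
  x[c(1, 13), 2] <- 1       # 1/12 and 1/10: removed
  x[13:15, 3] <- 1          # 3/10 wheat, ceil(10/3) = 4: removed
  fm <- make_fm(x)
  out <- quiet(filter_class_occurrence(fm, md, 1 / 3))
  expect_equal(ncol(out$intensity), 1)
  expect_equal(out$mz, fm$mz[1])
  # idempotent
  expect_equal(quiet(filter_class_occurrence(out, md, 1 / 3))$intensity,
               out$intensity)
  md_bad <- md; md_bad$starch_class[1] <- ""
  expect_error(quiet(filter_class_occurrence(fm, md_bad, 1 / 3)), "class")
})

lc_metadata <- function(n, qc_every = 5) {
  is_qc <- seq_len(n) %% qc_every == 0
  data.frame(sample_id = paste0("I", seq_len(n)), injection_order = seq_len(n),
             is_qc = is_qc,
             starch_class = ifelse(is_qc, NA, "barley"))
}

test_that("LOWESS correction flattens a linear drift to < 1% QC CV", {
  n <- 60
  md <- lc_metadata(n)
  drift <- 1 + 0.01 * seq_len(n)
  x <- cbind(1000 * drift, 500 * drift)
  rownames(x) <- md$sample_id
  fm <- make_fm(x)
  out <- lowess_qc_normalize(fm, md, span = 0.9)
  qc <- md$is_qc
  for (j in 1:2) {
    cv <- sd(out$intensity[qc, j]) / mean(out$intensity[qc, j])
    expect_lt(cv, 0.01)
    # pre-correction CV was much larger
    expect_gt(sd(fm$intensity[qc, j]) / mean(fm$intensity[qc, j]), 0.1)
  }
})

test_that("LOWESS is the identity for constant QCs and commutes with scaling", {
  n <- 40
  md <- lc_metadata(n)
  set.seed(4)
  x <- matrix(rlnorm(n * 3, 10, 0.3), n, 3)
  x[md$is_qc, ] <- rep(c(800, 1200, 300), each = sum(md$is_qc))
  rownames(x) <- md$sample_id
  fm <- make_fm(x)
  out <- lowess_qc_normalize(fm, md, span = 0.7)
  expect_equal(out$intensity, fm$intensity, tolerance = 1e-9)
  # correcting c*x equals c*corrected(x)
  fm2 <- make_fm(x * 3.7)
  drift_md <- md
  xd <- x * (1 + 0.02 * seq_len(n))
  rownames(xd) <- md$sample_id
  a <- lowess_qc_normalize(make_fm(xd * 2.5), drift_md, 0.7)$intensity
  b <- lowess_qc_normalize(make_fm(xd), drift_md, 0.7)$intensity * 2.5
  expect_equal(a, b, tolerance = 1e-9)
  expect_error(lowess_qc_normalize(fm, transform(md, is_qc = FALSE), 0.5),
               "QC")
})

test_that("drift correction reduces QC CV on a synthetic LC cohort", {
  ch <- generate_cohort(cohort_config(n_samples_per_class = 10,
                                      n_background_formulas = 120,
                                      drift_slope = 0.02, seed = 9,
                                      mode = "lc_tof"))
  fm <- ch$features
  out <- quiet(lowess_qc_normalize(fm, ch$metadata, span = 0.5))
  qc <- ch$metadata$is_qc[match(rownames(fm$intensity),
                                ch$metadata$sample_id)]
  cv <- function(v) sd(v) / mean(v)
  pre <- apply(fm$intensity[qc, ], 2, cv)
  post <- apply(out$intensity[qc, ], 2, cv)
  expect_lt(median(post, na.rm = TRUE), median(pre, na.rm = TRUE))
})

test_that("scale_transform centers, scales, and drops constants as promised", {
  set.seed(2)
  x <- matrix(rlnorm(200, 5, 1), 20, 10)
  uv <- scale_transform(x, scaling = "unit_variance")
  expect_true(all(abs(colMeans(uv)) < 1e-9))
  expect_equal(unname(apply(uv, 2, sd)), rep(1, 10), tolerance = 1e-9)
  # pareto: a column with SD 4 ends at SD 2
  x2 <- x; x2[, 1] <- scale(x2[, 1]) * 4 + 100
  par <- scale_transform(x2, scaling = "pareto")
  expect_equal(unname(sd(par[, 1])), 2, tolerance = 1e-9)
  # none: centered only
  nn <- scale_transform(x, scaling = "none")
  expect_equal(unname(nn[, 3]), unname(x[, 3] - mean(x[, 3])))
  # constant column dropped with a message
  x3 <- cbind(x, 7)
  expect_message(st <- scale_transform(x3), "constant")
  expect_equal(ncol(st), 10)
  # total-intensity normalization equalizes row sums before centering
  tin <- scale_transform(x, scaling = "none", normalization = "total_intensity")
  expect_true(is.matrix(tin))
  expect_error(scale_transform(matrix(numeric(0), 0, 0)), "empty")
})
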
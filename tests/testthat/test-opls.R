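sep_data <- function(n_per = 10, p = 6, delta = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * p, sd = 0.01), 2 * n_per, p)
  y <- rep(c("a", "b"), each = n_per)
  x[y == "b", 1] <- x[y == "b", 1] + delta
  list(x = x, y = y)
}

test_that("a noiseless separable two-class problem is fitted perfectly", {
  d <- sep_data(delta = 5, seed = 2)
  m <- oplsda(d$x, d$y, n_predictive = 1, n_orthogonal = 0, scale = "none")
  expect_gte(m$r2y, 0.999)
  t1 <- m$scores[, 1]
  expect_true(max(t1[d$y == "a"]) < min(t1[d$y == "b"]) ||
              min(t1[d$y == "a"]) > max(t1[d$y == "b"]))
})

test_that("with no orthogonal components the fit equals an eigen-PLS2 oracle", {
  set.seed(8)
  X <- scale(matrix(rnorm(8 * 5), 8, 5), scale = FALSE)
  y <- factor(rep(c("a", "b", "c"), length.out = 8))
  Y <- scale(stats::model.matrix(~ y - 1), scale = FALSE)
  m <- oplsda(X, y, n_predictive = 2, n_orthogonal = 0, scale = "none")
  T_oracle <- pls2_eigen_oracle(X, Y, 2)
  for (a in 1:2) {
    ratio <- abs(cor(m$scores[, a], T_oracle[, a]))
    expect_gt(ratio, 1 - 1e-8)
    expect_equal(abs(m$scores[, a]), abs(T_oracle[, a]), tolerance = 1e-6)
  }
})

test_that("an orthogonal component absorbs class-uncorrelated structure", {
  d <- sep_data(n_per = 16, p = 8, delta = 3, seed = 5)
  clean <- oplsda(d$x, d$y, 1, 0, scale = "none")
  # structured variation exactly uncorrelated with class (balanced within
  # class) whose loading overlaps the predictive direction: the classic case
  # an orthogonal component exists to remove
  t_o <- rep(c(1, -1), 16)
  x2 <- d$x
  x2[, 1] <- x2[, 1] + 2 * t_o
  x2[, 5] <- x2[, 5] + 6 * t_o
  dirty <- oplsda(x2, d$y, 1, 1, scale = "none")
  rel <- sqrt(sum((dirty$loadings - clean$loadings)^2)) /
    sqrt(sum(clean$loadings^2))
  expect_lt(rel, 1e-3)
  # without the filter the contamination shows up in the loadings
  dirty0 <- oplsda(x2, d$y, 1, 0, scale = "none")
  rel0 <- sqrt(sum((dirty0$loadings - clean$loadings)^2)) /
    sqrt(sum(clean$loadings^2))
  expect_gt(rel0, 10 * rel)
  # the orthogonal score recovered the planted structure
  expect_gt(abs(cor(dirty$scores_ortho[, 1], t_o)), 0.99)
})

test_that("scores are mutually orthogonal and the fit is reproducible", {
  ch <- small_cohort(seed = 2, npc = 8, nbg = 200)
  fm <- quiet(align_masses(ch$peaklists, 0.5))
  y <- factor(ch$metadata$starch_class)
  m1 <- oplsda(fm$intensity, y, 3, 1)
  m2 <- oplsda(fm$intensity, y, 3, 1)
  expect_identical(m1$scores, m2$scores)      # bit-for-bit deterministic
  G <- crossprod(cbind(m1$scores, m1$scores_ortho))
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)), 1e-8 * max(diag(G)))
  # R2Y non-decreasing in the number of predictive components
  r2 <- vapply(1:3, function(a) oplsda(fm$intensity, y, a, 0)$r2y, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
  # sign canonicalization: largest-magnitude weight entry is positive
  for (a in seq_len(ncol(m1$weights))) {
    w <- m1$weights[, a]
    expect_gt(w[which.max(abs(w))], 0)
  }
})

test_that("degenerate inputs are rejected", {
  d <- sep_data()
  xc <- d$x; xc[, 3] <- 42
  expect_error(oplsda(xc, d$y), "constant")
  expect_error(oplsda(d$x[c(1, 2, 11, 12), ], d$y[c(1, 2, 11, 12)], 2, 2),
               "too few samples")
  expect_error(oplsda(d$x, rep("a", nrow(d$x))), "2 classes")
})

test_that("projecting training samples reproduces their scores; contracts hold", {
  d <- sep_data(n_per = 12, p = 7, seed = 3)
  colnames(d$x) <- paste0("f", 1:7)
  m <- oplsda(d$x, d$y, 1, 1)
  pr <- predict(m, d$x)
  expect_equal(pr$scores, m$scores, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(as.character(pr$class), d$y)
  bad <- cbind(d$x, extra = 1)
  expect_error(predict(m, bad), "unknown")
  expect_error(predict(m, d$x[, 1:5]), "missing")
  # coef/fitted/residuals are consistent
  expect_equal(dim(coef(m)), c(7L, 2L))
  expect_equal(fitted(m) + residuals(m),
               unname(stats::model.matrix(~ factor(d$y) - 1)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Q2 of pure noise is near zero and never exceeds R2Y", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(100 * 20), 100, 20)
    y <- factor(rep(c("a", "b", "c", "d"), each = 25)[sample.int(100)])
    cv <- cross_validate(x, y, 3, 0, folds = 7, seed = s, scale = "none")
    expect_lte(cv$q2, 0.1)
    m <- oplsda(x, y, 3, 0, scale = "none")
    expect_lte(cv$q2, m$r2y)
  }
})

test_that("cross-validation is fold-deterministic and guards class loss", {
  d <- sep_data(n_per = 10, p = 5, seed = 6)
  cv1 <- cross_validate(d$x, d$y, 1, 0, folds = 5, seed = 42, scale = "none")
  cv2 <- cross_validate(d$x, d$y, 1, 0, folds = 5, seed = 42, scale = "none")
  expect_identical(cv1$q2, cv2$q2)
  expect_identical(cv1$fold, cv2$fold)
  y_rare <- c(rep("a", 19), "b")
  expect_error(cross_validate(d$x, y_rare, 1, 0, folds = 5, seed = 1,
                              scale = "none"),
               "class")
})

test_that("CV-ANOVA follows the F construction and its boundary rule", {
  cv <- list(press = 40, sstot = 100, n = 50, k = 4,
             n_predictive = 3, n_orthogonal = 1)
  out <- cv_anova(cv)
  d1 <- 4 * 4; d2 <- 4 * (50 - 1 - 4)
  f_expect <- ((100 - 40) / d1) / (40 / d2)
  expect_equal(out$f, f_expect)
  expect_equal(out$p, pf(f_expect, d1, d2, lower.tail = FALSE))
  # PRESS >= SSTot: no evidence, p = 1 (not an error)
  expect_equal(cv_anova(list(press = 100, sstot = 100, n = 50, k = 4,
                             n_predictive = 3, n_orthogonal = 1))$p, 1)
})

test_that("random-label CV-ANOVA keeps its type-I error near nominal", {
  hits <- 0; reps <- 50
  for (s in seq_len(reps)) {
    set.seed(1000 + s)
    x <- matrix(rnorm(40 * 10), 40, 10)
    y <- factor(sample(rep(c("a", "b"), each = 20)))
    cv <- cross_validate(x, y, 1, 0, folds = 4, seed = s, scale = "none")
    if (cv_anova(cv)$p < 0.05) hits <- hits + 1
  }
  expect_lte(hits / reps, 0.15)
})

test_that("Hotelling threshold matches the closed form and flags ~5%", {
  # A = 1: threshold equals the squared t-bound scaled by (n+1)/n
  n <- 80
  set.seed(12)
  s1 <- matrix(rnorm(n), n, 1)
  ht <- hotelling_t2(s1, 0.05)
  t_based <- (n + 1) / n * qt(1 - 0.05 / 2, n - 1)^2
  expect_equal(ht$threshold, t_based, tolerance = 1e-9)
  # distributional behaviour in 2-D
  for (s in 1:3) {
    set.seed(s)
    sc <- matrix(rnorm(500 * 2), 500, 2)
    fr <- mean(hotelling_t2(sc, 0.05)$flagged)
    expect_gte(fr, 0.02); expect_lte(fr, 0.09)
  }
  # a gross outlier is always flagged and a single-pass refit drops it
  d <- sep_data(n_per = 10, p = 4, seed = 9)
  m <- oplsda(d$x, d$y, 1, 0, scale = "none")
  sc <- m$scores
  sc[1, ] <- sc[1, ] + 100 * max(abs(sc))
  expect_true(hotelling_t2(sc)$flagged[1])
  m2 <- quiet(refit_without_outliers(m, alpha = 0.05))
  expect_s3_class(m2, "oplsda")
  expect_lte(nrow(m2$x), nrow(m$x))
})

test_that("with_seed restores the caller's RNG state", {
  set.seed(123); before <- .Random.seed
  invisible(with_seed(9, runif(5)))
  expect_identical(.Random.seed, before)
  expect_identical(with_seed(9, runif(3)), with_seed(9, runif(3)))
})
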
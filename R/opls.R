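#' Orthogonal partial least squares discriminant analysis
#'
#' Fits a multi-class OPLS-DA model: orthogonal (class-uncorrelated) variation
#' is estimated and deflated from X first, then a NIPALS PLS2 model with
#' `n_predictive` components is fitted against the one-hot class response.
#' The algorithm is fully deterministic: NIPALS iterations start from the
#' response column with the largest variance (ties broken by lowest index) and
#' each component's weight vector is sign-canonicalized so that its
#' largest-magnitude entry is positive.
#'
#' @param x Numeric matrix, samples x features (raw or pre-transformed
#'   intensities; centering/scaling is done internally and stored so new data
#'   can be projected).
#' @param y Factor (or coercible) of class labels, length `nrow(x)`.
#' @param n_predictive Number of predictive components; default one fewer than
#'   the number of classes.
#' @param n_orthogonal Number of orthogonal components removed before the
#'   predictive fit.
#' @param scale Column scaling: `"pareto"` (default; divide by the square
#'   root of the column SD, the usual compromise for MS intensities),
#'   `"unit_variance"`, or `"none"`. Columns are always mean-centered.
#' @return Object of class `"oplsda"`: weights/loadings/scores for the
#'   predictive (`weights`, `loadings`, `scores`, `y_loadings`) and orthogonal
#'   (`weights_ortho`, `loadings_ortho`, `scores_ortho`) parts, the projection
#'   matrix `rotation`, stored `center`/`scale_`, `classes`, `r2y`, and the
#'   training data (`x`, `y`) for refits and cross-validation.
#' @seealso [cross_validate()], [cv_anova()], [hotelling_t2()],
#'   [predict.oplsda()], [class_loading_scores()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 8), 40)
#' y <- rep(c("a", "b"), each = 20)
#' x[y == "b", 1:2] <- x[y == "b", 1:2] + 3
#' m <- oplsda(x, y, n_predictive = 1, n_orthogonal = 0)
#' m$r2y
#' @export
oplsda <- function(x, y, n_predictive = NULL, n_orthogonal = 1,
                   scale = c("pareto", "unit_variance", "none")) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) != length(y)) stop("length(y) must equal nrow(x)")
  K <- nlevels(y)
  if (K < 2) stop("need at least 2 classes")
  if (is.null(n_predictive)) n_predictive <- K - 1
  if (n_predictive < 1) stop("`n_predictive` must be >= 1")
  n <- nrow(x)
  if (n <= n_predictive + n_orthogonal) stop("too few samples for the requested components")

  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant X column(s): ", paste(utils::head(which(sds == 0), 5),
                                         collapse = ", "),
         " - drop them in preprocessing")
  }
  ctr <- colMeans(x)
  scl <- switch(scale, unit_variance = sds, pareto = sqrt(sds),
                none = rep(1, ncol(x)))
  Xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  ym <- colMeans(Y)
  Yc <- sweep(Y, 2, ym)

  fit <- .opls_core(Xs, Yc, n_predictive, n_orthogonal)
  sse <- sum((Yc - fit$T %*% t(fit$C))^2)
  r2y <- 1 - sse / sum(Yc^2)

  centroids <- apply(fit$T, 2, function(t) tapply(t, y, mean))
  if (is.null(dim(centroids))) centroids <- matrix(centroids, ncol = 1,
                                                   dimnames = list(levels(y)))

  structure(list(
    n_predictive = n_predictive, n_orthogonal = fit$n_orthogonal,
    weights = fit$W, loadings = fit$P, scores = fit$T, y_loadings = fit$C,
    weights_ortho = fit$Wo, loadings_ortho = fit$Po, scores_ortho = fit$To,
    rotation = fit$R, center = ctr, scale_ = scl, scale_mode = scale,
    classes = levels(y), class_centroids = centroids,
    y_means = ym, r2y = r2y, x = x, y = y
  ), class = "oplsda")
}

# one NIPALS PLS2 component on (already deflated) X, Y
.nipals_component <- function(X, Y, tol = 1e-12, max_iter = 1000) {
  vy <- apply(Y, 2, stats::var)
  u <- Y[, which.max(vy)]
  t_old <- rep(0, nrow(X))
  for (it in seq_len(max_iter)) {
    w <- crossprod(X, u)
    w <- w / sqrt(sum(w^2))
    t <- drop(X %*% w)
    cc <- drop(crossprod(Y, t)) / sum(t^2)
    u <- drop(Y %*% cc) / sum(cc^2)
    if (sum((t - t_old)^2) <= tol^2 * sum(t^2)) break
    t_old <- t
  }
  w <- drop(w)
  s <- sign(w[which.max(abs(w))])
  if (s < 0) { w <- -w; t <- -t; cc <- -cc }
  list(w = w, t = t, c = cc)
}

# orthogonal filtering followed by PLS2; X, Y centered
.opls_core <- function(X, Y, A, O) {
  p <- ncol(X); K <- ncol(Y); n <- nrow(X)
  Wo <- Po <- matrix(0, p, 0); To <- matrix(0, n, 0)
  o_done <- 0L
  for (j in seq_len(O)) {
    Wy <- qr.Q(qr(crossprod(X, Y)))          # basis of the predictive span
    comp <- .nipals_component(X, Y)
    pl <- drop(crossprod(X, comp$t)) / sum(comp$t^2)
    wo <- pl - drop(Wy %*% crossprod(Wy, pl))
    nrm <- sqrt(sum(wo^2))
    if (nrm < 1e-10 * max(sqrt(sum(pl^2)), 1e-300)) {
      warning("orthogonal component ", j, " is null; stopping at ", o_done)
      break
    }
    wo <- wo / nrm
    s <- sign(wo[which.max(abs(wo))])
    if (s < 0) wo <- -wo
    to <- drop(X %*% wo)
    po <- drop(crossprod(X, to)) / sum(to^2)
    X <- X - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
    o_done <- j
  }
  W <- P <- matrix(0, p, A); T <- matrix(0, n, A); C <- matrix(0, K, A)
  for (a in seq_len(A)) {
    comp <- .nipals_component(X, Y)
    pl <- drop(crossprod(X, comp$t)) / sum(comp$t^2)
    X <- X - tcrossprod(comp$t, pl)
    Y <- Y - tcrossprod(comp$t, comp$c)
    W[, a] <- comp$w; P[, a] <- pl; T[, a] <- comp$t; C[, a] <- comp$c
  }
  R <- W %*% solve(crossprod(P, W))
  list(W = W, P = P, T = T, C = C, Wo = Wo, Po = Po, To = To, R = R,
       n_orthogonal = o_done)
}

# project new (already scaled) data: strip orthogonal variation, then score
.opls_project <- function(model, Xs) {
  O <- model$n_orthogonal
  if (O > 0) {
    for (j in seq_len(O)) {
      to <- drop(Xs %*% model$weights_ortho[, j])
      Xs <- Xs - tcrossprod(to, model$loadings_ortho[, j])
    }
  }
  Xs %*% model$rotation
}

#' Predict class membership for new samples
#'
#' Applies the stored centering/scaling, removes the orthogonal components,
#' projects onto the predictive weights, and assigns each sample to the class
#' whose training centroid is nearest in predictive score space.
#'
#' @param object A fitted [oplsda()] model.
#' @param newdata Numeric matrix with the same feature columns as the training
#'   data (checked by name when both are named).
#' @param ... Unused.
#' @return List with `scores` (predictive scores), `class` (factor), and
#'   `y_pred` (class-membership predictions on the one-hot scale).
#' @export
predict.oplsda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  tr_names <- colnames(object$x)
  if (!is.null(tr_names) && !is.null(colnames(newdata))) {
    missing <- setdiff(tr_names, colnames(newdata))
    extra <- setdiff(colnames(newdata), tr_names)
    if (length(missing) || length(extra)) {
      stop("feature mismatch; missing: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ..." else "",
           "; unknown: ", paste(utils::head(extra, 5), collapse = ", "),
           if (length(extra) > 5) ", ..." else "")
    }
    newdata <- newdata[, tr_names, drop = FALSE]
  } else if (ncol(newdata) != ncol(object$x)) {
    stop("feature mismatch: expected ", ncol(object$x), " columns, got ",
         ncol(newdata))
  }
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale_, "/")
  Tn <- .opls_project(object, Xs)
  cen <- object$class_centroids
  d2 <- outer(rowSums(Tn^2), rowSums(cen^2), "+") - 2 * Tn %*% t(cen)
  cls <- factor(object$classes[apply(d2, 1, which.min)],
                levels = object$classes)
  y_pred <- sweep(Tn %*% t(object$y_loadings), 2, object$y_means, "+")
  colnames(y_pred) <- object$classes
  list(scores = Tn, class = cls, y_pred = y_pred)
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf(
    "<oplsda> %d samples, %d features, %d classes (%s)\n  %d predictive + %d orthogonal component(s), R2Y = %.4f\n",
    nrow(x$x), ncol(x$x), length(x$classes),
    paste(x$classes, collapse = ", "),
    x$n_predictive, x$n_orthogonal, x$r2y))
  invisible(x)
}

#' @export
summary.oplsda <- function(object, ...) {
  ans <- list(model = object,
              per_component = data.frame(
                component = seq_len(object$n_predictive),
                ssx = colSums(object$loadings^2) * colSums(object$scores^2),
                ssy = colSums(object$y_loadings^2) * colSums(object$scores^2)))
  class(ans) <- "summary.oplsda"
  ans
}

#' @export
print.summary.oplsda <- function(x, ...) {
  print(x$model)
  cat("per-component sums of squares:\n")
  print(x$per_component, row.names = FALSE)
  invisible(x)
}

#' @export
coef.oplsda <- function(object, ...) {
  b <- object$rotation %*% t(object$y_loadings)
  dimnames(b) <- list(colnames(object$x), object$classes)
  b
}

#' @export
fitted.oplsda <- function(object, ...) {
  sweep(object$scores %*% t(object$y_loadings), 2, object$y_means, "+")
}

#' @export
residuals.oplsda <- function(object, ...) {
  Y <- stats::model.matrix(~ object$y - 1)
  colnames(Y) <- object$classes
  Y - fitted(object)
}

#' Score plot of an OPLS-DA model
#'
#' @param x A fitted [oplsda()] model.
#' @param components Two predictive components to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.oplsda <- function(x, components = c(1, 2), ...) {
  if (x$n_predictive == 1) {
    graphics::stripchart(split(x$scores[, 1], x$y), vertical = TRUE,
                         method = "jitter", pch = 19,
                         ylab = "predictive score t1", ...)
    return(invisible(x))
  }
  cl <- as.integer(x$y)
  graphics::plot(x$scores[, components[1]], x$scores[, components[2]],
                 col = cl, pch = 19,
                 xlab = paste0("t", components[1]),
                 ylab = paste0("t", components[2]), ...)
  graphics::legend("topright", legend = x$classes,
                   col = seq_along(x$classes), pch = 19, cex = 0.8)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey")
  invisible(x)
}

#' Stratified cross-validation of an OPLS-DA model
#'
#' Q2 = 1 - PRESS/SSTot over held-out one-hot predictions. Folds are
#' stratified by class and deterministic under `seed`; each fold's
#' centering/scaling is recomputed on its training split, and features that
#' are constant within a training split are ignored for that fold.
#'
#' @param x,y As in [oplsda()].
#' @param n_predictive,n_orthogonal,scale Model settings, as in [oplsda()].
#' @param folds Number of CV segments (default 7).
#' @param seed Integer seed controlling the fold assignment.
#' @return Object of class `"opls_cv"`: `q2`, `press`, `sstot`, `fold` (fold
#'   index per sample), held-out `y_pred` and `class_pred`, `accuracy`, and the
#'   component counts.
#' @export
cross_validate <- function(x, y, n_predictive = NULL, n_orthogonal = 1,
                           folds = 7, seed = 1,
                           scale = c("pareto", "unit_variance", "none")) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  n <- nrow(x); K <- nlevels(y)
  if (is.null(n_predictive)) n_predictive <- K - 1
  if (folds < 2) stop("`folds` must be >= 2")
  if (folds > min(table(y))) {
    stop("`folds` exceeds the smallest class size; reduce folds")
  }

  fold <- integer(n)
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  for (f in seq_len(folds)) {
    if (nlevels(droplevels(y[fold != f])) < K) {
      stop("fold ", f, " would lose an entire class from training; reduce folds")
    }
  }

  Y <- stats::model.matrix(~ y - 1)
  sstot <- sum(sweep(Y, 2, colMeans(Y))^2)
  y_pred <- matrix(NA_real_, n, K, dimnames = list(rownames(x), levels(y)))
  class_pred <- factor(rep(NA, n), levels = levels(y))
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    sds <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    use <- sds > 0
    m <- oplsda(x[tr, use, drop = FALSE], y[tr],
                n_predictive = n_predictive, n_orthogonal = n_orthogonal,
                scale = scale)
    pr <- predict(m, x[te, use, drop = FALSE])
    y_pred[te, ] <- pr$y_pred
    class_pred[te] <- pr$class
  }
  press <- sum((Y - y_pred)^2)
  structure(list(q2 = 1 - press / sstot, press = press, sstot = sstot,
                 fold = fold, y_pred = y_pred, class_pred = class_pred,
                 accuracy = mean(class_pred == y),
                 n = n, k = K,
                 n_predictive = n_predictive, n_orthogonal = n_orthogonal),
            class = "opls_cv")
}

#' @export
print.opls_cv <- function(x, ...) {
  cat(sprintf("<opls_cv> Q2 = %.4f (PRESS %.2f / SSTot %.2f), CV accuracy %.1f%%\n",
              x$q2, x$press, x$sstot, 100 * x$accuracy))
  invisible(x)
}

#' CV-ANOVA significance test
#'
#' F-test of the cross-validated predictions against the variation of the
#' one-hot response around its mean:
#' `F = ((SSTot - PRESS)/d1) / (PRESS/d2)` with per-element degrees of freedom
#' `d1 = K * A` and `d2 = K * (N - 1 - A)`, where `K` is the number of
#' classes and `A` the total number of model components (predictive +
#' orthogonal). The p-value is the upper tail of the F distribution. If PRESS
#' >= SSTot (the model predicts no better than the mean), p = 1.
#'
#' @param cv An [cross_validate()] result, or a list with `press`, `sstot`,
#'   `n`, `k`, `n_predictive`, `n_orthogonal`.
#' @return List with `f`, `df1`, `df2`, `p`.
#' @export
cv_anova <- function(cv) {
  a <- cv$n_predictive + cv$n_orthogonal
  d1 <- cv$k * a
  d2 <- cv$k * (cv$n - 1 - a)
  if (d2 <= 0) stop("no residual degrees of freedom")
  if (cv$press >= cv$sstot) {
    return(list(f = 0, df1 = d1, df2 = d2, p = 1))
  }
  f <- ((cv$sstot - cv$press) / d1) / (cv$press / d2)
  list(f = f, df1 = d1, df2 = d2,
       p = stats::pf(f, d1, d2, lower.tail = FALSE))
}

#' Hotelling's T-squared outlier flags for a score matrix
#'
#' `T2_i = (s_i - mean)' S^-1 (s_i - mean)` with `S` the score covariance;
#' sample i is flagged when `T2_i` exceeds
#' `A (n-1) (n+1) / (n (n-A)) * qf(1 - alpha, A, n - A)`.
#'
#' @param scores Numeric matrix, samples x A components.
#' @param alpha Significance level (default 0.05, the 95% ellipse).
#' @return List with `t2`, `threshold`, and logical `flagged`.
#' @export
hotelling_t2 <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  n <- nrow(scores); A <- ncol(scores)
  if (n <= A) stop("need more samples than components")
  S <- stats::cov(scores)
  if (abs(det(S)) < 1e-300) stop("singular score covariance")
  t2 <- stats::mahalanobis(scores, colMeans(scores), S)
  thr <- A * (n - 1) * (n + 1) / (n * (n - A)) *
    stats::qf(1 - alpha, A, n - A)
  list(t2 = t2, threshold = thr, flagged = t2 > thr)
}

#' Refit a model once with Hotelling outliers removed
#'
#' Single-pass exclusion: samples outside the `1 - alpha` Hotelling ellipse of
#' the predictive scores are dropped and the model refitted once (never
#' iterated), with the removals logged.
#'
#' @param model A fitted [oplsda()] model.
#' @param alpha Hotelling significance level.
#' @return Refitted `"oplsda"` model (the input model if nothing is flagged),
#'   with attribute `"removed"` listing dropped sample indices.
#' @export
refit_without_outliers <- function(model, alpha = 0.05) {
  ht <- hotelling_t2(model$scores, alpha)
  if (!any(ht$flagged)) {
    attr(model, "removed") <- integer()
    return(model)
  }
  keep <- !ht$flagged
  message("refit_without_outliers: removing ", sum(ht$flagged),
          " sample(s): ", paste(which(ht$flagged), collapse = ", "))
  out <- oplsda(model$x[keep, , drop = FALSE], model$y[keep],
                n_predictive = model$n_predictive,
                n_orthogonal = model$n_orthogonal,
                scale = model$scale_mode)
  attr(out, "removed") <- which(ht$flagged)
  out
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded package functions never perturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
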
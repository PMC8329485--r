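# Independent oracles used by the test suite. Each implements a different
# algorithm than the package code it cross-checks.

# --- formula enumeration oracle: pre-enumerated library + range query -------
# Enumerates every chemically plausible formula up to `max_mass` once and
# answers queries by interval lookup, instead of solving for H per mass.
make_enumeration_oracle <- function(max_mass = 520,
                                    bounds = default_element_bounds()) {
  cmax <- min(bounds[["C"]], floor(max_mass / 12))
  hmax <- min(bounds[["H"]], floor(max_mass / 1.007), 3 * cmax + 3)
  hetero <- expand.grid(N = 0:bounds[["N"]], O = 0:bounds[["O"]],
                        S = 0:bounds[["S"]], P = 0:bounds[["P"]],
                        Cl = 0:bounds[["Cl"]], KEEP.OUT.ATTRS = FALSE)
  ch <- as.matrix(expand.grid(C = 1:cmax, H = 0:hmax,
                              KEEP.OUT.ATTRS = FALSE))
  ch_mass <- drop(ch %*% ELEMENT_MASSES[colnames(ch)])
  chunks <- vector("list", nrow(hetero))
  for (k in seq_len(nrow(hetero))) {
    hrow <- as.matrix(hetero[k, , drop = FALSE])
    hmass <- drop(hrow %*% ELEMENT_MASSES[colnames(hrow)])
    pre <- ch_mass + hmass <= max_mass
    if (!any(pre)) next
    g <- cbind(ch[pre, , drop = FALSE],
               matrix(rep(hrow, each = sum(pre)), ncol = 5,
                      dimnames = list(NULL, colnames(hetero))))
    g <- g[, c("C", "H", "N", "O", "S", "P", "Cl"), drop = FALSE]
    g <- g[chemical_filters(g), , drop = FALSE]
    if (nrow(g)) chunks[[k]] <- g
  }
  g <- do.call(rbind, chunks[!vapply(chunks, is.null, logical(1))])
  mass <- drop(g %*% ELEMENT_MASSES[colnames(g)])
  o <- order(mass)
  g <- g[o, , drop = FALSE]; mass <- mass[o]
  function(mz, adduct, tol_ppm) {
    shift <- adduct_shifts()[[adduct]]
    target <- mz - shift
    tol <- tol_ppm * 1e-6 * mz
    lo <- findInterval(target - tol, mass) + 1L
    hi <- findInterval(target + tol, mass)
    if (hi < lo) return(character(0))
    sel <- g[lo:hi, , drop = FALSE]
    if (adduct == "[M+Cl]-") sel <- sel[sel[, "Cl"] == 0, , drop = FALSE]
    if (nrow(sel) == 0) return(character(0))
    formula_string(sel)
  }
}

# --- PLS2 oracle: eigendecomposition kernel algorithm -----------------------
# Weights from the dominant eigenvector of X'YY'X (closed-form per component),
# not from NIPALS power iterations.
pls2_eigen_oracle <- function(X, Y, A) {
  n <- nrow(X)
  T <- matrix(0, n, A)
  for (a in seq_len(A)) {
    M <- crossprod(crossprod(Y, X))        # X'Y Y'X
    w <- eigen(M, symmetric = TRUE)$vectors[, 1]
    t <- drop(X %*% w)
    p <- drop(crossprod(X, t)) / sum(t^2)
    c <- drop(crossprod(Y, t)) / sum(t^2)
    X <- X - tcrossprod(t, p)
    Y <- Y - tcrossprod(t, c)
    T[, a] <- t
  }
  T
}

# --- exhaustive fragment-matching oracle ------------------------------------
# Best-scoring one-to-one matching over all candidate pair subsets, by
# recursive branch-and-bound-free enumeration (fine for <= 6 fragments).
exhaustive_match_score <- function(a, b, frag_tol = 0.01) {
  va <- sqrt(a$fragments$intensity); va <- va / sqrt(sum(va^2))
  vb <- sqrt(b$fragments$intensity); vb <- vb / sqrt(sum(vb^2))
  dmz <- outer(a$fragments$mz, b$fragments$mz, "-")
  shift <- a$precursor_mz - b$precursor_mz
  ok <- abs(dmz) <= frag_tol | abs(dmz - shift) <= frag_tol
  pairs <- which(ok, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(0)
  best <- 0
  recurse <- function(k, used_a, used_b, acc) {
    if (k > nrow(pairs)) { best <<- max(best, acc); return() }
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used_a[i] && !used_b[j]) {
      ua <- used_a; ua[i] <- TRUE; ub <- used_b; ub[j] <- TRUE
      recurse(k + 1, ua, ub, acc + va[i] * vb[j])
    }
    recurse(k + 1, used_a, used_b, acc)
  }
  recurse(1, logical(length(va)), logical(length(vb)), 0)
  min(best, 1)
}

# small convenience: a quick DI cohort for tests that do not need full scale
small_cohort <- function(seed = 1, npc = 10, nbg = 300, ...) {
  generate_cohort(cohort_config(n_samples_per_class = npc,
                                n_background_formulas = nbg,
                                seed = seed, ...))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
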
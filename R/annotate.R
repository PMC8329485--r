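#' Default element bounds for formula enumeration
#'
#' Upper element counts used when searching formula space for an exact mass,
#' following common ultra-high-resolution FTICR practice for small-molecule
#' metabolomes below m/z 1,000.
#'
#' @return Named integer vector of maximal counts per element.
#' @export
default_element_bounds <- function() {
  c(C = 66L, H = 126L, N = 7L, O = 27L, S = 3L, P = 2L, Cl = 1L)
}

# Cache of the heteroatom/C/O enumeration grid, keyed by the bounds.
.enum_cache <- new.env(parent = emptyenv())

# Grid over all elements except H, with precomputed partial masses. H is then
# solved per query mass, which keeps the search exhaustive but vectorized.
.enum_grid <- function(bounds) {
  key <- paste(bounds, collapse = "_")
  if (!is.null(.enum_cache[[key]])) return(.enum_cache[[key]])
  g <- expand.grid(C = 1:bounds[["C"]], O = 0:bounds[["O"]],
                   N = 0:bounds[["N"]], S = 0:bounds[["S"]],
                   P = 0:bounds[["P"]], Cl = 0:bounds[["Cl"]],
                   KEEP.OUT.ATTRS = FALSE)
  g <- as.matrix(g)
  base <- g %*% ELEMENT_MASSES[colnames(g)]
  res <- list(grid = g, base = drop(base))
  .enum_cache[[key]] <- res
  res
}

#' Enumerate candidate molecular formulas for an exact ion mass
#'
#' Exhaustively searches CHNOSPCl formula space (within element bounds) for
#' neutral formulas whose ion m/z under each candidate adduct falls within a
#' ppm tolerance of the measured mass. Candidates must pass
#' [chemical_filters()]; they are ranked by absolute mass error. The top
#' candidate is promoted to an assignment only if it is the sole candidate or
#' its absolute error is at least 3-fold smaller than the runner-up's — the
#' package's operational definition of an unambiguous formula.
#'
#' @param mz Measured ion m/z (single positive number).
#' @param adducts Character vector of adducts to consider (see
#'   [adduct_shifts()]).
#' @param tol_ppm Mass tolerance in ppm (> 0).
#' @param bounds Named vector of element bounds, default
#'   [default_element_bounds()].
#' @return Object of class `"annotation"`: list with `mz`, `candidates`
#'   (data.frame: formula, adduct, theo_mz, error_ppm, ranked), `assigned`
#'   (one-row data.frame or `NULL`), and `provenance = "enumeration"`.
#' @examples
#' enumerate_formulas(335.22278, "[M-H]-", tol_ppm = 0.5)$assigned$formula
#' @export
enumerate_formulas <- function(mz, adducts = c("[M-H]-", "[M+Cl]-"),
                               tol_ppm = 0.5,
                               bounds = default_element_bounds()) {
  if (!is.numeric(mz) || length(mz) != 1 || mz <= 0) stop("`mz` must be a single positive number")
  if (tol_ppm <= 0) stop("`tol_ppm` must be > 0")
  shifts <- adduct_shifts()
  if (!all(adducts %in% names(shifts))) stop("unknown adduct(s)")
  eg <- .enum_grid(bounds)
  mH <- ELEMENT_MASSES[["H"]]
  tol_da <- tol_ppm * 1e-6 * mz

  cand <- list()
  for (ad in adducts) {
    target <- mz - shifts[[ad]]                 # neutral mass to explain
    h <- round((target - eg$base) / mH)
    ok <- h >= 0 & h <= bounds[["H"]] &
      abs(eg$base + h * mH - target) <= tol_da
    if (!any(ok)) next
    counts <- cbind(eg$grid[ok, , drop = FALSE], H = h[ok])
    counts <- counts[, .ELEMENTS, drop = FALSE]
    keep <- chemical_filters(counts)
    # chloride adducts of chlorinated neutrals are excluded: Cl in the ion is
    # accounted to the adduct, and the Cl <= 1 bound applies to the ion
    if (ad == "[M+Cl]-") keep <- keep & counts[, "Cl"] == 0
    if (!any(keep)) next
    counts <- counts[keep, , drop = FALSE]
    theo <- drop(counts %*% ELEMENT_MASSES) + shifts[[ad]]
    cand[[ad]] <- data.frame(
      formula = formula_string(counts),
      adduct = ad,
      theo_mz = theo,
      error_ppm = (mz - theo) / theo * 1e6,
      stringsAsFactors = FALSE
    )
  }
  candidates <- if (length(cand)) do.call(rbind, cand) else
    data.frame(formula = character(), adduct = character(),
               theo_mz = numeric(), error_ppm = numeric())
  rownames(candidates) <- NULL
  if (nrow(candidates)) {
    candidates <- candidates[order(abs(candidates$error_ppm),
                                   candidates$formula), , drop = FALSE]
    rownames(candidates) <- NULL
  }
  assigned <- NULL
  if (nrow(candidates) == 1) {
    assigned <- candidates[1, , drop = FALSE]
  } else if (nrow(candidates) > 1) {
    e1 <- abs(candidates$error_ppm[1]); e2 <- abs(candidates$error_ppm[2])
    if (e1 * 3 <= e2) assigned <- candidates[1, , drop = FALSE]
  }
  structure(list(mz = mz, candidates = candidates, assigned = assigned,
                 provenance = "enumeration"),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> m/z %.5f: %d candidate(s)", x$mz, nrow(x$candidates)))
  if (!is.null(x$assigned)) {
    cat(sprintf("; assigned %s %s (%.3f ppm, %s)\n", x$assigned$formula,
                x$assigned$adduct, x$assigned$error_ppm, x$provenance))
  } else cat("; unassigned\n")
  invisible(x)
}

#' Align peak lists across samples into a feature matrix
#'
#' Pools all peaks, sorts by m/z, and cuts the sorted list wherever the gap
#' between adjacent masses exceeds `tol_ppm` (single-linkage clustering).
#' Clusters spanning more than `3 * tol_ppm` are split at their largest
#' internal gap rather than silently merged. Each sample contributes at most
#' one peak per feature (highest intensity wins); absent features are
#' zero-filled. The consensus m/z is the intensity-weighted mean.
#'
#' @param peaklists List of [peaklist()] objects (or a single one).
#' @param tol_ppm Gap threshold in ppm.
#' @return A [feature_matrix()] (samples x features) with consensus m/z.
#' @export
align_masses <- function(peaklists, tol_ppm = 1) {
  if (inherits(peaklists, "peaklist")) peaklists <- list(peaklists)
  if (length(peaklists) == 0) stop("need at least one peak list")
  if (tol_ppm <= 0) stop("`tol_ppm` must be > 0")
  sample_ids <- vapply(peaklists, function(p) p$sample_id, character(1))
  if (anyDuplicated(sample_ids)) stop("duplicate sample_id among peak lists")
  pooled <- do.call(rbind, lapply(peaklists, function(p) {
    data.frame(mz = p$peaks$mz, intensity = p$peaks$intensity,
               sample = p$sample_id)
  }))
  ord <- order(pooled$mz)
  pooled <- pooled[ord, ]
  n <- nrow(pooled)
  if (n == 0) stop("no peaks to align")

  # single-linkage: break where relative gap exceeds tol
  gap_ppm <- c(Inf, diff(pooled$mz) / pooled$mz[-n] * 1e6)
  cluster <- cumsum(gap_ppm > tol_ppm)

  # split clusters spanning > 3 * tol at their largest internal gap
  repeat {
    spans <- tapply(pooled$mz, cluster, function(v) (max(v) - min(v)) / mean(v) * 1e6)
    wide <- names(spans)[spans > 3 * tol_ppm]
    if (!length(wide)) break
    for (cl in wide) {
      idx <- which(cluster == as.integer(cl))
      gaps <- diff(pooled$mz[idx])
      cut <- which.max(gaps)
      message("align_masses: splitting over-wide cluster at m/z ",
              signif(pooled$mz[idx[cut]], 8))
      cluster[idx[(cut + 1):length(idx)]] <- max(cluster) + 1
    }
    # renumber by position to keep clusters contiguous and ordered
    cluster <- match(cluster, unique(cluster))
  }
  cluster <- match(cluster, unique(cluster))

  consensus <- as.numeric(tapply(seq_len(n), cluster, function(i) {
    stats::weighted.mean(pooled$mz[i], pooled$intensity[i])
  }))
  nfeat <- length(consensus)
  feat_of_row <- cluster
  mat <- matrix(0, nrow = length(sample_ids), ncol = nfeat,
                dimnames = list(sample_ids, NULL))
  # highest intensity per (sample, feature) wins
  o <- order(pooled$intensity)   # ascending: later assignment overwrites
  mat[cbind(match(pooled$sample[o], sample_ids), feat_of_row[o])] <-
    pooled$intensity[o]
  feature_matrix(mat, mz = consensus)
}

#' Propagate formula annotations through a mass-difference network
#'
#' NetCalc-style annotation: starting from seed assignments, any unassigned
#' mass that differs from an assigned mass by a library reaction difference
#' (within tolerance) is proposed the seed formula plus/minus the reaction's
#' formula delta. Proposals with negative element counts, failing
#' [chemical_filters()], or whose recomputed ion m/z deviates from the measured
#' mass by more than the tolerance are rejected. Conflicting proposals from
#' different paths leave the mass ambiguous (all proposals listed, none
#' assigned). Propagation iterates to a fixed point.
#'
#' @param mzs Numeric vector of measured ion m/z values (one adduct assumed,
#'   default deprotonation, so ion mass differences equal neutral differences).
#' @param seeds Data frame with columns `mz` and `formula` (seed assignments),
#'   or a list of `"annotation"` objects with non-`NULL` `assigned`.
#' @param library A [reaction_library()]; defaults to the built-in one.
#' @param tol_ppm Tolerance in ppm; the absolute window for a pair is
#'   `tol_ppm * 1e-6 * mean(pair)`.
#' @param adduct Adduct linking measured m/z to neutral formulas.
#' @return List of `"annotation"` objects, one per input mass, with
#'   `provenance` `"seed"` or `"network"`; unannotated masses have empty
#'   candidate sets.
#' @export
network_annotation <- function(mzs, seeds, library = builtin_reaction_library(),
                               tol_ppm = 1, adduct = "[M-H]-") {
  if (nrow(library) == 0) stop("empty reaction library")
  if (is.list(seeds) && !is.data.frame(seeds)) {
    seeds <- do.call(rbind, lapply(seeds, function(a) {
      if (is.null(a$assigned)) return(NULL)
      data.frame(mz = a$mz, formula = a$assigned$formula)
    }))
  }
  if (is.null(seeds) || nrow(seeds) == 0) stop("need at least one assigned seed")
  n <- length(mzs)
  counts <- matrix(NA_real_, nrow = n, ncol = length(.ELEMENTS),
                   dimnames = list(NULL, .ELEMENTS))
  prov <- rep(NA_character_, n)
  ambiguous <- vector("list", n)
  for (k in seq_len(nrow(seeds))) {
    i <- which.min(abs(mzs - seeds$mz[k]))
    if (abs(mzs[i] - seeds$mz[k]) / mzs[i] * 1e6 > tol_ppm) next
    counts[i, ] <- parse_formula(seeds$formula[k])[1, ]
    prov[i] <- "seed"
  }
  if (!any(prov == "seed", na.rm = TRUE)) stop("no seed matches any input mass")

  deltas <- reaction_deltas(library)        # matrix reactions x elements
  dmass <- library$mass_delta
  frontier <- which(!is.na(prov))
  while (length(frontier)) {
    new_frontier <- integer()
    for (i in frontier) {
      fi <- counts[i, ]
      for (r in seq_along(dmass)) {
        for (sgn in c(1, -1)) {
          target <- mzs[i] + sgn * dmass[r]
          tol_da <- tol_ppm * 1e-6 * (mzs[i] + target) / 2
          js <- which(abs(mzs - target) <= tol_da)
          for (j in js) {
            if (j == i || !is.na(prov[j])) next
            g <- fi + sgn * deltas[r, ]
            if (any(g < 0)) next
            if (!chemical_filters(matrix(g, 1, dimnames = list(NULL, .ELEMENTS)))) next
            theo <- sum(g * ELEMENT_MASSES) + adduct_shifts()[[adduct]]
            if (abs(theo - mzs[j]) / mzs[j] * 1e6 > tol_ppm) next
            fs <- formula_string(matrix(g, 1, dimnames = list(NULL, .ELEMENTS)))
            prior <- ambiguous[[j]]
            if (is.null(prior)) {
              ambiguous[[j]] <- fs
            } else if (!fs %in% prior) {
              ambiguous[[j]] <- c(prior, fs)
            }
          }
        }
      }
    }
    # commit unambiguous proposals, queue them as the next frontier
    for (j in seq_len(n)) {
      if (!is.na(prov[j]) || is.null(ambiguous[[j]])) next
      if (length(ambiguous[[j]]) == 1) {
        counts[j, ] <- parse_formula(ambiguous[[j]])[1, ]
        prov[j] <- "network"
        new_frontier <- c(new_frontier, j)
      }
    }
    frontier <- new_frontier
  }

  lapply(seq_len(n), function(i) {
    if (!is.na(prov[i])) {
      f <- formula_string(matrix(counts[i, ], 1, dimnames = list(NULL, .ELEMENTS)))
      theo <- sum(counts[i, ] * ELEMENT_MASSES) + adduct_shifts()[[adduct]]
      cdf <- data.frame(formula = f, adduct = adduct, theo_mz = theo,
                        error_ppm = (mzs[i] - theo) / theo * 1e6)
      structure(list(mz = mzs[i], candidates = cdf,
                     assigned = cdf, provenance = prov[i]),
                class = "annotation")
    } else {
      props <- ambiguous[[i]]
      cdf <- if (is.null(props)) {
        data.frame(formula = character(), adduct = character(),
                   theo_mz = numeric(), error_ppm = numeric())
      } else {
        theo <- ion_mz(props, adduct)
        data.frame(formula = props, adduct = adduct, theo_mz = theo,
                   error_ppm = (mzs[i] - theo) / theo * 1e6)
      }
      structure(list(mz = mzs[i], candidates = cdf, assigned = NULL,
                     provenance = "network"),
                class = "annotation")
    }
  })
}
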
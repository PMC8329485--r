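#' Modified-cosine similarity between two MS2 spectra
#'
#' Cosine similarity of square-root-intensity fragment vectors under a greedy
#' best-match pairing. Two fragments may be paired if their m/z agree within
#' `frag_tol` (shared fragment) or if their m/z difference equals the
#' precursor difference within `frag_tol` (shared neutral loss / modified
#' match). Each fragment is used at most once; candidate pairs are taken in
#' descending order of their intensity product. The score is in [0, 1], is
#' symmetric, and is invariant to rescaling either spectrum.
#'
#' @param a,b [ms2spectrum()] objects with at least one fragment each.
#' @param frag_tol Fragment m/z tolerance in Da (default 0.01, ToF-scale).
#' @param method `"modified_cosine"` (default) or `"cosine"` (direct matches
#'   only).
#' @return Similarity in [0, 1].
#' @export
spectral_similarity <- function(a, b, frag_tol = 0.01,
                                method = c("modified_cosine", "cosine")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "ms2spectrum"), inherits(b, "ms2spectrum"))
  if (nrow(a$fragments) == 0 || nrow(b$fragments) == 0) stop("empty spectrum")
  if (frag_tol <= 0) stop("`frag_tol` must be > 0")
  va <- sqrt(a$fragments$intensity); va <- va / sqrt(sum(va^2))
  vb <- sqrt(b$fragments$intensity); vb <- vb / sqrt(sum(vb^2))
  dmz <- outer(a$fragments$mz, b$fragments$mz, "-")
  match_ok <- abs(dmz) <= frag_tol
  if (method == "modified_cosine") {
    shift <- a$precursor_mz - b$precursor_mz
    match_ok <- match_ok | abs(dmz - shift) <= frag_tol
  }
  idx <- which(match_ok, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  prod <- va[idx[, 1]] * vb[idx[, 2]]
  o <- order(-prod, idx[, 1], idx[, 2])
  used_a <- logical(length(va)); used_b <- logical(length(vb))
  score <- 0
  for (k in o) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    score <- score + prod[k]
  }
  min(score, 1)
}

#' Build an MS2 spectral-similarity network
#'
#' All-pairs [spectral_similarity()] with edges kept at or above the cutoff;
#' connected components are labeled as clusters on the vertices.
#'
#' @param spectra List of [ms2spectrum()] objects (>= 2, unique feature ids).
#' @param cutoff Similarity cutoff in (0, 1] (default 0.65).
#' @param frag_tol Fragment tolerance in Da.
#' @param node_attrs Optional data frame of per-spectrum attributes (class
#'   tags etc.), one row per spectrum.
#' @return Undirected igraph of class `"spectral_network"` with vertex
#'   attributes `name`, `precursor_mz`, `cluster` and edge attribute
#'   `similarity`.
#' @export
build_similarity_network <- function(spectra, cutoff = 0.65, frag_tol = 0.01,
                                     node_attrs = NULL) {
  if (length(spectra) < 2) stop("need at least 2 spectra")
  if (cutoff <= 0 || cutoff > 1) stop("`cutoff` must be in (0, 1]")
  ids <- vapply(spectra, function(s) s$feature_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate feature ids among spectra")
  n <- length(spectra)
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- spectral_similarity(spectra[[i]], spectra[[j]], frag_tol)
      if (s >= cutoff) {
        edges[[length(edges) + 1L]] <-
          data.frame(from = ids[i], to = ids[j], similarity = s)
      }
    }
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), similarity = numeric())
  vdf <- data.frame(
    name = ids,
    precursor_mz = vapply(spectra, function(s) s$precursor_mz, numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(node_attrs)) {
    stopifnot(nrow(node_attrs) == n)
    vdf <- cbind(vdf, node_attrs)
  }
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  igraph::V(g)$cluster <- igraph::components(g)$membership
  class(g) <- c("spectral_network", class(g))
  g
}

#' @export
print.spectral_network <- function(x, ...) {
  comp <- igraph::components(x)
  cat(sprintf("<spectral_network> %d spectra, %d edges, %d cluster(s) of size >= 2\n",
              igraph::vcount(x), igraph::ecount(x), sum(comp$csize >= 2)))
  invisible(x)
}
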
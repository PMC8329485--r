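#' Build a mass-difference network
#'
#' Connects nodes whose difference corresponds to a library reaction. In
#' formula mode (character/matrix nodes), an edge requires the element-count
#' difference to equal a library delta exactly. In mass mode (numeric nodes),
#' an edge requires `|Δmass - mass_delta| <= tol_ppm * 1e-6 * sqrt(mz_a*mz_b)`
#' (geometric-mean denominator, symmetric in the pair). Multiple matching
#' reactions yield parallel labeled edges. The graph is undirected; exports
#' orient edges lower-mass-first.
#'
#' @param nodes Character vector of formulas, a formula count matrix, or a
#'   numeric vector of masses. Optionally named (names become node ids;
#'   formula strings or the mass values are used otherwise).
#' @param library A [reaction_library()].
#' @param tol_ppm Tolerance for mass-mode edges.
#' @param node_attrs Optional data frame of per-node attributes (class tags,
#'   intensities) attached to the vertices; one row per node.
#' @return Undirected igraph with vertex attributes `name`, `mass` (and any
#'   `node_attrs`), and edge attributes `reaction`, `observed_delta`, `error`.
#' @export
build_mdin <- function(nodes, library = builtin_reaction_library(),
                       tol_ppm = 1, node_attrs = NULL) {
  if (nrow(library) == 0) stop("empty reaction library")
  if (tol_ppm <= 0) stop("`tol_ppm` must be > 0")

  formula_mode <- is.character(nodes) || is.matrix(nodes)
  if (formula_mode) {
    counts <- as_formula_matrix(nodes)
    ids <- if (is.character(nodes) && !is.null(names(nodes)) &&
               all(nzchar(names(nodes)))) names(nodes) else formula_string(counts)
    masses <- formula_mass(counts)
  } else if (is.numeric(nodes)) {
    ids <- if (!is.null(names(nodes))) names(nodes) else
      sprintf("%.5f", nodes)
    masses <- as.numeric(nodes)
  } else stop("nodes must be all formulas or all masses, not mixed")
  n <- length(masses)
  if (n < 1) stop("need at least one node")
  if (anyDuplicated(ids)) stop("duplicate node ids")

  deltas <- reaction_deltas(library)
  edges <- list()
  if (n >= 2) {
    o <- order(masses)
    ms <- masses[o]
    # generous Da window for the binary search; the exact (pair-dependent)
    # tolerance is applied inside
    win <- max(0.02, tol_ppm * 1e-6 * max(ms) * 2)
    for (r in seq_len(nrow(library))) {
      dm <- library$mass_delta[r]
      for (ia in seq_len(n)) {
        a <- o[ia]
        target <- ms[ia] + dm
        j1 <- findInterval(target - win, ms) + 1L
        j2 <- findInterval(target + win, ms)
        if (j2 < j1) next
        for (ib in j1:j2) {
          if (ib <= ia) next
          b <- o[ib]
          tol_da <- tol_ppm * 1e-6 * sqrt(ms[ia] * ms[ib])
          if (formula_mode) {
            ok <- all(counts[b, ] - counts[a, ] == deltas[r, ])
            err <- 0
          } else {
            err <- ms[ib] - ms[ia] - dm
            ok <- abs(err) <= tol_da
          }
          if (ok) {
            edges[[length(edges) + 1L]] <- data.frame(
              from = ids[a], to = ids[b], reaction = library$name[r],
              observed_delta = ms[ib] - ms[ia], error = err)
          }
        }
      }
    }
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), reaction = character(),
               observed_delta = numeric(), error = numeric())
  vdf <- data.frame(name = ids, mass = masses, stringsAsFactors = FALSE)
  if (!is.null(node_attrs)) {
    stopifnot(nrow(node_attrs) == n)
    vdf <- cbind(vdf, node_attrs)
  }
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  class(g) <- c("mdin", class(g))
  g
}

#' Extract a neighborhood subnetwork
#'
#' Induced subgraph of all nodes within a given graph distance of any seed
#' node.
#'
#' @param graph Graph from [build_mdin()] or [build_similarity_network()].
#' @param seed_nodes Character vector of node names present in the graph.
#' @param radius Non-negative integer graph distance.
#' @return Induced igraph subgraph (same class as the input).
#' @export
subnetwork <- function(graph, seed_nodes, radius = 1) {
  stopifnot(igraph::is_igraph(graph))
  vn <- igraph::V(graph)$name
  missing <- setdiff(seed_nodes, vn)
  if (length(missing)) stop("seed node(s) not in graph: ",
                            paste(missing, collapse = ", "))
  d <- igraph::distances(graph, v = seed_nodes)
  keep <- vn[apply(d, 2, min) <= radius]
  sub <- igraph::induced_subgraph(graph, keep)
  class(sub) <- class(graph)
  sub
}

#' @export
print.mdin <- function(x, ...) {
  cat(sprintf("<mdin> %d nodes, %d edges, %d reaction type(s)\n",
              igraph::vcount(x), igraph::ecount(x),
              length(unique(igraph::E(x)$reaction))))
  invisible(x)
}
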
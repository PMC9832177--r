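# Graph statistics for partial-correlation networks: closeness, betweenness
# and expected influence centrality, and the small-worldness index.

#' Centrality table for a weighted signed network
#'
#' Path-based metrics convert edge weights to lengths `1/|w|` and use
#' shortest paths: closeness is `(n-1) / sum(distances to reachable nodes)`
#' (0 for isolates), betweenness counts shortest paths through a node with
#' fractional credit for ties, and expected influence is the signed row sum
#' of edge weights. Standardized (z-scored) columns accompany the raw ones.
#'
#' @param network A `ggm_network`.
#' @return Data frame of class `centrality_table`, one row per node.
#' @export
centrality <- function(network) {
  w <- network$weights
  p <- nrow(w)
  nodes <- network$node_names
  ei <- rowSums(w)
  if (sum(w != 0) > 0) {
    g <- ggm_igraph(network)
    len <- 1 / abs(igraph::E(g)$weight)
    D <- igraph::distances(g, weights = len)
    btw <- igraph::betweenness(g, weights = len, directed = FALSE)
  } else {
    D <- matrix(Inf, p, p); diag(D) <- 0
    btw <- rep(0, p)
  }
  clo <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else (p - 1) / sum(d)
  }, 0)
  z <- function(v) {
    s <- stats::sd(v)
    if (s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
  }
  out <- data.frame(node = nodes, closeness = clo, betweenness = btw,
                    expected_influence = ei,
                    closeness_z = z(clo), betweenness_z = z(btw),
                    expected_influence_z = z(ei),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Small-worldness index of a network
#'
#' Binarizes the network at nonzero edges and compares its global
#' transitivity `C` and average shortest path length `L` (largest connected
#' component, unweighted) with random-graph expectations
#' `C_rand = density` and `L_rand = ln(n_nodes) / ln(mean degree)`:
#' `SWI = (C / C_rand) / (L / L_rand)`. Values above 1 indicate small-world
#' structure; 3 is the stricter tier.
#'
#' @param network A `ggm_network` (or adjacency matrix) with at least 4
#'   nodes and 1 edge.
#' @return List with `swi`, `C`, `L`, `C_rand`, `L_rand`, `mean_degree`,
#'   `small_world` (SWI > 1), `small_world_strict` (SWI >= 3), `defined`.
#' @export
small_worldness <- function(network) {
  adj <- if (inherits(network, "ggm_network")) network$weights != 0 else
    network != 0
  diag(adj) <- FALSE
  p <- nrow(adj)
  if (p < 4) stop("small-worldness needs at least 4 nodes")
  if (!any(adj)) stop("small-worldness needs at least 1 edge")
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected")
  deg <- igraph::degree(g)
  mean_deg <- mean(deg)
  if (mean_deg <= 1) {
    return(list(swi = NA_real_, C = NA_real_, L = NA_real_,
                C_rand = NA_real_, L_rand = NA_real_,
                mean_degree = mean_deg, small_world = NA,
                small_world_strict = NA, defined = FALSE))
  }
  C <- igraph::transitivity(g, type = "global")
  if (is.nan(C)) C <- 0
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  L <- igraph::mean_distance(sub, directed = FALSE)
  C_rand <- igraph::edge_density(g)
  L_rand <- log(p) / log(mean_deg)
  swi <- (C / C_rand) / (L / L_rand)
  list(swi = swi, C = C, L = L, C_rand = C_rand, L_rand = L_rand,
       mean_degree = mean_deg, small_world = swi > 1,
       small_world_strict = swi >= 3, defined = TRUE)
}
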
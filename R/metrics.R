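#' Nodal clustering coefficient
#'
#' For a node with degree `k` and `e` edges among its neighbors, the
#' clustering coefficient is `2e / (k (k - 1))`: the fraction of
#' neighbor pairs that are themselves connected. Nodes with degree < 2
#' have coefficient 0.
#'
#' @param graph A [binary_graph()].
#' @param node Node label or index.
#' @return Clustering coefficient in `[0, 1]`.
#' @export
node_clustering <- function(graph, node) {
  stopifnot(inherits(graph, "binary_graph"))
  if (is.character(node)) {
    v <- match(node, graph$roi_labels)
    if (is.na(v)) stop("unknown node '", node, "'")
  } else {
    v <- as.integer(node)
    if (v < 1L || v > nrow(graph$adjacency)) stop("unknown node ", node)
  }
  ci <- unname(igraph::transitivity(as_igraph(graph), type = "local",
                                    vids = v))
  if (is.nan(ci) || is.na(ci)) 0 else ci
}

#' Network clustering coefficient Cp
#'
#' Arithmetic mean of the nodal clustering coefficients over all nodes of
#' the network (nodes of degree < 2 contribute 0); quantifies local
#' interconnectivity.
#'
#' @param graph A [binary_graph()].
#' @return Cp in `[0, 1]`.
#' @export
network_clustering <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  ci <- igraph::transitivity(as_igraph(graph), type = "local")
  ci[is.nan(ci) | is.na(ci)] <- 0
  mean(ci)
}

#' Characteristic path length Lp
#'
#' Mean shortest-path length (in edges) over node pairs. On disconnected
#' graphs, `convention = "connected_pairs"` (default) averages over
#' connected pairs only and records the number of excluded pairs in the
#' `"excluded_pairs"` attribute; `convention = "largest_component"`
#' restricts to the largest connected component.
#'
#' @param graph A [binary_graph()] with at least one edge.
#' @param convention Handling of disconnected node pairs.
#' @return Lp (numeric, >= 1), with attribute `excluded_pairs`.
#' @export
characteristic_path_length <- function(graph,
                                       convention = c("connected_pairs",
                                                      "largest_component")) {
  stopifnot(inherits(graph, "binary_graph"))
  convention <- match.arg(convention)
  g <- as_igraph(graph)
  if (igraph::ecount(g) == 0L) stop("graph has no edges; Lp undefined")
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  if (convention == "largest_component") {
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
    excluded <- n * (n - 1) / 2 - length(keep) * (length(keep) - 1) / 2
  } else {
    excluded <- n * (n - 1) / 2 - sum(comp$csize * (comp$csize - 1) / 2)
  }
  lp <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  if (!is.finite(lp)) stop("no connected node pairs; Lp undefined")
  structure(lp, excluded_pairs = as.integer(excluded))
}

#' Size of the largest connected component
#'
#' @param graph A [binary_graph()].
#' @return Node count of the largest component (1 for an empty graph with
#'   at least one node).
#' @export
largest_component_size <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  max(igraph::components(as_igraph(graph))$csize)
}

#' Lowest density giving a fully connected graph
#'
#' Scans the density sweep from below and returns the smallest density at
#' which the binarized graph's largest component spans all N nodes. This
#' density is the conventional choice of "fixed density" for nodal
#' metrics: the sparsest graph in which every ROI participates.
#'
#' @param matrix A `connectivity_matrix`.
#' @param sweep A [density_sweep()].
#' @return The selected density (fraction).
#' @export
lowest_full_connection_density <- function(matrix, sweep = density_sweep()) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  n <- length(matrix$roi_labels)
  for (d in sweep_densities(sweep)) {
    g <- binarize_fixed_density(matrix, d)
    if (largest_component_size(g) == n) return(d)
  }
  stop("no density in the sweep fully connects the graph; ",
       "widen the sweep (d_max = ", sweep$d_max, ")")
}

#' Betweenness centrality
#'
#' Freeman betweenness of every node: the number of shortest paths
#' between other node pairs passing through the node, with fractional
#' credit split over multiple geodesics, endpoints excluded, and each
#' unordered pair counted once.
#'
#' @param graph A [binary_graph()].
#' @return Named numeric vector `B` (one entry per node).
#' @export
betweenness_centrality <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  b <- igraph::betweenness(as_igraph(graph), directed = FALSE)
  names(b) <- graph$roi_labels
  b
}

#' Normalized betweenness and hub flags
#'
#' Normalizes betweenness as `b_i = B_i / mean(B)`, so b averages to 1
#' over the network, and flags nodes with `b_i > hub_threshold`
#' (default 1.5) as functional hubs. When the mean betweenness is 0
#' (e.g. a complete graph) b is undefined: all values are `NA`, no hubs,
#' with a warning.
#'
#' @param graph A [binary_graph()].
#' @param hub_threshold Hub cutoff on b (default 1.5).
#' @return A data frame of class `nodal_metrics` with columns `roi`, `B`,
#'   `b`, `is_hub`, and attribute `density_used` (the graph's density).
#' @export
normalized_betweenness <- function(graph, hub_threshold = 1.5) {
  B <- betweenness_centrality(graph)
  mB <- mean(B)
  if (mB == 0) {
    warning("mean betweenness is 0; normalized betweenness undefined")
    b <- rep(NA_real_, length(B))
    hub <- rep(FALSE, length(B))
  } else {
    b <- B / mB
    hub <- b > hub_threshold
  }
  out <- data.frame(roi = graph$roi_labels, B = unname(B), b = unname(b),
                    is_hub = unname(hub))
  attr(out, "density_used") <- graph$density
  class(out) <- c("nodal_metrics", class(out))
  out
}

#' Global metrics of a binary graph
#'
#' @param graph A [binary_graph()].
#' @param lp_convention Passed to [characteristic_path_length()].
#' @return One-row data frame with `Cp`, `Lp`, `largest_component`,
#'   `density`.
#' @export
global_metrics <- function(graph, lp_convention = "connected_pairs") {
  data.frame(Cp = network_clustering(graph),
             Lp = as.numeric(characteristic_path_length(graph,
                                                        lp_convention)),
             largest_component = largest_component_size(graph),
             density = graph$density)
}
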
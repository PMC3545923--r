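#' Degree-preserving rewiring of a binary graph
#'
#' Randomizes a graph by repeated double-edge swaps (edges a-b, c-d
#' replaced by a-d, c-b when neither a self-loop nor a duplicate edge
#' would result), the standard construction of a random reference network
#' with exactly the original degree sequence. The default budget of
#' `10 * |E|` swap attempts is the usual mixing heuristic.
#'
#' @param graph A [binary_graph()] with at least 2 edges.
#' @param n_swaps Number of swap attempts (default `10 * |E|`).
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is consumed.
#' @return A rewired [binary_graph()] with identical degree sequence.
#' @export
rewire_preserving_degree <- function(graph, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(graph, "binary_graph"))
  g <- as_igraph(graph)
  ne <- igraph::ecount(g)
  if (ne < 2L) stop("need at least 2 edges to rewire")
  if (is.null(n_swaps)) n_swaps <- 10L * ne
  do_rewire <- function() igraph::rewire(
    g, with = igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
  g2 <- if (is.null(seed)) do_rewire() else withr::with_seed(seed, do_rewire())
  A <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
  out <- binary_graph(A, graph$roi_labels)
  if (!identical(colSums(out$adjacency), colSums(graph$adjacency)))
    stop("internal error: rewiring changed the degree sequence")
  out
}

#' Mean clustering and path length of matched random references
#'
#' Generates `n_random` independent degree-preserving rewirings of the
#' graph (each from `10 * |E|` swap attempts) and returns the means of
#' their clustering coefficient and characteristic path length, the
#' reference values against which small-worldness is judged. References
#' are not forced to be connected; Lp uses the same convention as for the
#' real graph.
#'
#' @param graph A [binary_graph()].
#' @param n_random Number of random references (study default 1000).
#' @param seed Integer seed for the reference ensemble.
#' @param lp_convention Passed to [characteristic_path_length()].
#' @return List with `Cp_rand`, `Lp_rand`, `n_random`, `seed`.
#' @export
random_reference_stats <- function(graph, n_random = 1000L, seed = 1L,
                                   lp_convention = "connected_pairs") {
  stopifnot(inherits(graph, "binary_graph"), n_random >= 1L)
  cp <- lp <- numeric(n_random)
  withr::with_seed(seed, {
    for (i in seq_len(n_random)) {
      ref <- rewire_preserving_degree(graph)
      cp[i] <- network_clustering(ref)
      lp[i] <- as.numeric(characteristic_path_length(ref, lp_convention))
    }
  })
  list(Cp_rand = mean(cp), Lp_rand = mean(lp),
       n_random = as.integer(n_random), seed = as.integer(seed))
}

#' Small-world indices gamma, lambda, sigma
#'
#' Compares a network's clustering and path length with the means of
#' degree-matched random references: `gamma = Cp / Cp_rand`,
#' `lambda = Lp / Lp_rand`, and the small-world index
#' `sigma = gamma / lambda`. A small-world network shows `gamma >> 1`
#' with `lambda ~ 1`, i.e. `sigma > 1`. When the reference clustering is
#' 0 (tree-like graphs) sigma is undefined and returned as `NA` with a
#' warning.
#'
#' @param graph A [binary_graph()].
#' @param n_random Number of random references (study default 1000).
#' @param seed Integer seed for the reference ensemble.
#' @param lp_convention Passed to [characteristic_path_length()].
#' @return Object of class `small_world` with fields `Cp`, `Lp`,
#'   `Cp_rand`, `Lp_rand`, `gamma`, `lambda`, `sigma`, `n_random`, `seed`.
#' @export
small_world_indices <- function(graph, n_random = 1000L, seed = 1L,
                                lp_convention = "connected_pairs") {
  stopifnot(inherits(graph, "binary_graph"))
  cp <- network_clustering(graph)
  lp <- as.numeric(characteristic_path_length(graph, lp_convention))
  ref <- random_reference_stats(graph, n_random, seed, lp_convention)
  if (ref$Cp_rand <= 0) {
    warning("reference clustering is 0; gamma and sigma undefined")
    gamma <- NA_real_
  } else {
    gamma <- cp / ref$Cp_rand
  }
  lambda <- lp / ref$Lp_rand
  structure(list(Cp = cp, Lp = lp,
                 Cp_rand = ref$Cp_rand, Lp_rand = ref$Lp_rand,
                 gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 n_random = ref$n_random, seed = ref$seed),
            class = "small_world")
}

#' @export
print.small_world <- function(x, ...) {
  cat("<small_world> gamma = ", signif(x$gamma, 4),
      ", lambda = ", signif(x$lambda, 4),
      ", sigma = ", signif(x$sigma, 4),
      "  (", x$n_random, " references)\n", sep = "")
  invisible(x)
}
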
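# Brute-force graph oracles in plain R (no igraph), used to cross-check
# the package's metric implementations on small graphs.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_clustering <- function(A, i) {
  nb <- which(A[i, ] == 1)
  k <- length(nb)
  if (k < 2) return(0)
  e <- sum(A[nb, nb]) / 2
  2 * e / (k * (k - 1))
}

oracle_cp <- function(A) {
  mean(vapply(seq_len(nrow(A)), function(i) oracle_clustering(A, i), 0))
}

oracle_lp <- function(A) {
  D <- oracle_distances(A)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

oracle_component_sizes <- function(A) {
  D <- oracle_distances(A)
  seen <- rep(FALSE, nrow(A))
  sizes <- integer(0)
  for (i in seq_len(nrow(A))) {
    if (seen[i]) next
    comp <- which(is.finite(D[i, ]))
    seen[comp] <- TRUE
    sizes <- c(sizes, length(comp))
  }
  sizes
}

# All geodesics between s and t, enumerated by pruned depth-first search.
oracle_geodesics <- function(A, s, t, D) {
  res <- list()
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      res[[length(res) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(A[v, ] == 1)) {
      if (!(w %in% path) && D[w, t] == D[v, t] - 1) recurse(c(path, w))
    }
  }
  recurse(s)
  res
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  B <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in seq.int(s + 1L, n)) {
      if (!is.finite(D[s, t])) next
      paths <- oracle_geodesics(A, s, t, D)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        B[interior] <- B[interior] + 1 / length(paths)
      }
    }
  }
  B
}

# Random connected graph on n nodes (adjacency matrix), retrying until
# connected under the oracle's own component check.
random_connected_adjacency <- function(n, p) {
  repeat {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
    A <- A + t(A)
    if (max(oracle_component_sizes(A)) == n) return(A)
  }
}

# Small named graphs used across tests.
graph_from_edges <- function(n, edges, labels = paste0("V", seq_len(n))) {
  A <- matrix(0, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  dimnames(A) <- list(labels, labels)
  binary_graph(A, labels)
}
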
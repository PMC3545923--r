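triangle <- graph_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))
star4 <- graph_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
path4 <- graph_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4)),
                          labels = c("A", "B", "C", "D"))
square_diag <- graph_from_edges(
  4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3)),
  labels = c("A", "B", "C", "D"))

test_that("nodal clustering matches hand-enumerated cases", {
  expect_equal(node_clustering(triangle, 1), 1)
  expect_equal(node_clustering(star4, 1), 0)   # star center
  expect_equal(node_clustering(star4, 2), 0)   # leaf, degree 1
  expect_equal(node_clustering(square_diag, "A"), 2 / 3)
  expect_equal(node_clustering(square_diag, "B"), 1)
  expect_error(node_clustering(triangle, "Z"), "unknown node")
})

test_that("network clustering averages over all nodes including low degree", {
  expect_equal(network_clustering(triangle), 1)
  expect_equal(network_clustering(star4), 0)
  expect_equal(network_clustering(square_diag), (2 / 3 + 1 + 2 / 3 + 1) / 4)
})

test_that("characteristic path length matches closed-form small cases", {
  k4 <- graph_from_edges(4, combn(4, 2, simplify = FALSE))
  expect_equal(as.numeric(characteristic_path_length(k4)), 1)
  p3 <- graph_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(as.numeric(characteristic_path_length(p3)), 4 / 3)
  c5 <- graph_from_edges(5, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                                 c(5, 1)))
  expect_equal(as.numeric(characteristic_path_length(c5)), 1.5)
})

test_that("disconnected pairs are excluded and counted", {
  two_tri <- graph_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3),
                                      c(4, 5), c(5, 6), c(4, 6)))
  lp <- characteristic_path_length(two_tri)
  expect_equal(as.numeric(lp), 1)
  expect_identical(attr(lp, "excluded_pairs"), 9L)
  lg <- characteristic_path_length(two_tri, "largest_component")
  expect_equal(as.numeric(lg), 1)
  empty <- binary_graph(matrix(0, 4, 4))
  expect_error(characteristic_path_length(empty), "no edges")
})

test_that("largest component size covers empty and disjoint graphs", {
  expect_equal(largest_component_size(binary_graph(matrix(0, 5, 5))), 1)
  two_tri_iso <- graph_from_edges(7, list(c(1, 2), c(2, 3), c(1, 3),
                                          c(4, 5), c(5, 6), c(4, 6)))
  expect_equal(largest_component_size(two_tri_iso), 3)
  k4 <- graph_from_edges(4, combn(4, 2, simplify = FALSE))
  expect_equal(largest_component_size(k4), 4)
})

test_that("betweenness matches hand-enumerated geodesic counts", {
  B <- betweenness_centrality(star4)
  expect_equal(unname(B), c(6, 0, 0, 0, 0))  # 6 leaf pairs via center
  k5 <- graph_from_edges(5, combn(5, 2, simplify = FALSE))
  expect_equal(unname(betweenness_centrality(k5)), rep(0, 5))
  Bp <- betweenness_centrality(path4)
  expect_equal(unname(Bp), c(0, 2, 2, 0))
})

test_that("normalized betweenness averages to 1 and flags hubs", {
  nm <- normalized_betweenness(star4)
  expect_equal(nm$b[1], 5)           # 6 / 1.2
  expect_true(nm$is_hub[1])
  expect_equal(nm$b[2], 0)
  expect_false(any(nm$is_hub[-1]))
  expect_equal(mean(nm$b), 1)
  c6 <- graph_from_edges(6, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                                 c(5, 6), c(6, 1)))
  nmc <- normalized_betweenness(c6)
  expect_equal(nmc$b, rep(1, 6))     # symmetry forces equality
  expect_false(any(nmc$is_hub))
  k4 <- graph_from_edges(4, combn(4, 2, simplify = FALSE))
  expect_warning(nmk <- normalized_betweenness(k4), "undefined")
  expect_true(all(is.na(nmk$b)))
  expect_false(any(nmk$is_hub))
})

test_that("metrics agree exactly with brute-force oracles on random graphs", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(4:7, 1)
    A <- random_connected_adjacency(n, runif(1, 0.3, 0.7))
    g <- binary_graph(A)
    for (i in seq_len(n))
      expect_equal(node_clustering(g, i), oracle_clustering(A, i))
    expect_equal(network_clustering(g), oracle_cp(A))
    expect_equal(as.numeric(characteristic_path_length(g)), oracle_lp(A))
    expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(A),
                 tolerance = 1e-12)
  }
})

test_that("adding an edge never increases a pairwise distance", {
  set.seed(7)
  for (rep in 1:10) {
    A <- random_connected_adjacency(7, 0.4)
    D1 <- oracle_distances(A)
    miss <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
    if (nrow(miss) == 0) next
    e <- miss[sample(nrow(miss), 1), ]
    A2 <- A
    A2[e[1], e[2]] <- A2[e[2], e[1]] <- 1
    D2 <- oracle_distances(A2)
    expect_true(all(D2 <= D1 + 1e-12))
  }
})

test_that("lowest full-connection density finds the first spanning sweep point", {
  # matrix whose 89 strongest coefficients form a spanning star:
  # full connection already at the sweep's first density (6% of 90 nodes
  # keeps 240 edges >= the 89 star edges).
  n <- 90
  R <- matrix(0, n, n)
  R[1, 2:n] <- R[2:n, 1] <- 0.9
  cm <- connectivity_matrix(R)
  expect_equal(lowest_full_connection_density(cm), 0.06)

  # one ROI uncorrelated with everything and a sweep too narrow: error
  set.seed(12)
  co <- simulate_cohort(brain_config(n_per_group = 25L, groups = "CN"))
  cm2 <- partial_correlation_matrix(global_normalize(co))
  cm2$r[5, ] <- cm2$r[, 5] <- 0
  expect_error(
    lowest_full_connection_density(cm2, density_sweep(0.01, 0.02, 0.01)),
    "widen")

  # monotonicity: once fully connected, larger sweep densities stay so
  cm3 <- partial_correlation_matrix(global_normalize(co))
  d0 <- lowest_full_connection_density(cm3, density_sweep(0.06, 0.40, 0.02))
  for (d in seq(d0, 0.40, by = 0.02)) {
    g <- binarize_fixed_density(cm3, d)
    expect_equal(largest_component_size(g), 90)
  }
})
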
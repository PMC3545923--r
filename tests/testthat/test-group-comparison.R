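test_that("identical cohorts give a zero observed difference", {
  co <- simulate_cohort(tiny_config(n_per_group = 20L, groups = "A"))
  for (m in c("Cp", "Lp")) {
    d <- observed_group_difference(co, co, m, 0.15)
    expect_equal(unname(d), 0)
  }
  db <- observed_group_difference(co, co, "b", 0.15)
  expect_length(db, 20L)
  expect_true(all(db == 0))
})

test_that("the permutation null is reproducible and centered near zero", {
  cfg <- tiny_config(n_per_group = 25L, seed = 71L)
  co <- simulate_cohort(cfg)
  cA <- subset_group(co, "A")
  cB <- subset_group(co, "B")
  n1 <- permutation_null(cA, cB, "Cp", 0.15, n_perm = 10, seed = 4)
  n2 <- permutation_null(cA, cB, "Cp", 0.15, n_perm = 10, seed = 4)
  expect_identical(n1, n2)
  n200 <- permutation_null(cA, cB, "Cp", 0.15, n_perm = 200, seed = 5)
  se <- sd(n200) / sqrt(200)
  expect_lt(abs(mean(n200)), 2 * se + 1e-8)
})

test_that("significance evaluation follows the add-one counting rule", {
  ev <- evaluate_significance(0, rnorm(100), alternative = "observed")
  expect_equal(ev$p, 1)
  expect_false(ev$significant)

  null <- seq_len(4999) / 5000   # observed above every null value
  ev2 <- evaluate_significance(2, null)
  expect_equal(ev2$p, 1 / 5000)
  expect_true(ev2$significant)

  # observed at the null median
  null3 <- seq(-1, 1, length.out = 999)
  ev3 <- evaluate_significance(1e-9, null3)
  expect_lt(abs(ev3$p - 0.5), 0.01)
  expect_false(ev3$significant)

  # mirrored lower tail, both fixed and data-driven
  ev4 <- evaluate_significance(-2, -null, alternative = "less")
  expect_equal(ev4$p, 1 / 5000)
  expect_equal(ev4$direction, -1)
  ev5 <- evaluate_significance(-2, -null, alternative = "observed")
  expect_equal(ev5$p, ev4$p)

  # the data-driven direction doubles the realized tail probability:
  # under a symmetric null, either extreme is called significant
  sym <- seq(-1, 1, length.out = 1999)
  hi <- evaluate_significance(0.995, sym, alternative = "observed")
  lo <- evaluate_significance(-0.995, sym, alternative = "observed")
  expect_true(hi$significant && lo$significant)
  expect_false(evaluate_significance(-0.995, sym)$significant)
})

test_that("permutations preserve group sizes through the pooled cohort", {
  cfg <- tiny_config(n_per_group = 15L, seed = 81L)
  co <- simulate_cohort(cfg)
  cA <- subset_group(co, "A")
  cB <- subset_group(co, "B")
  nb <- permutation_null(cA, cB, "b", 0.2, n_perm = 3, seed = 2)
  expect_identical(dim(nb), c(3L, 20L))
  expect_error(permutation_null(
    subset_group(co, "A"), cB, "Cp", 0.15, n_perm = 1, seed = 1), NA)
  small <- roi_cohort(cA$values[1:5, ], cA$covariates[1:5, ],
                      cA$group[1:5], cA$roi_labels)
  expect_error(permutation_null(small, cB, "Cp", 0.15, 1, 1),
               "covariate")
})

test_that("focal perturbation lowers clustering and is detected in direction", {
  cfg <- cohort_config(group_sizes = c(G = 100L), seed = 91L)
  co <- suppressMessages(simulate_cohort(cfg))
  pert <- apply_perturbation(co, "focal", default_focal_rois(), 0.3,
                             seed = 7L)
  d <- observed_group_difference(pert, co, "Cp", 0.15)
  expect_lt(unname(d), 0)
})

test_that("observed difference magnitude grows with perturbation strength", {
  # attenuation levels chosen inside the non-saturated range: below
  # ~0.5 the perturbed edges already rank under the density threshold,
  # so further attenuation cannot widen the clustering gap
  diffs <- sapply(c(0.9, 0.7, 0.45), function(a) {
    vals <- sapply(1:5, function(s) {
      cfg <- cohort_config(group_sizes = c(G = 100L), seed = 7100L + s)
      co <- suppressMessages(simulate_cohort(cfg))
      pert <- apply_perturbation(co, "focal", default_focal_rois(), a,
                                 seed = s)
      unname(observed_group_difference(co, pert, "Cp", 0.15))
    })
    mean(vals)
  })
  expect_true(all(diff(diffs) > 0))  # stronger attenuation, larger gap
})

test_that("sweep comparison covers every density without adjustment", {
  cfg <- tiny_config(n_per_group = 20L, seed = 111L)
  co <- simulate_cohort(cfg)
  cA <- subset_group(co, "A")
  cB <- subset_group(co, "B")
  sweep <- density_sweep(0.10, 0.20, 0.05)
  tab <- sweep_comparison(cA, cB, metrics = c("Cp", "Lp"), sweep = sweep,
                          n_perm = 20, seed = 3)
  expect_identical(nrow(tab), 2L * 3L)
  expect_named(tab, c("metric", "density", "observed_diff",
                      "critical_value", "p", "significant"))
  expect_true(all(is.finite(tab$p)))
  sig <- attr(tab, "significant_densities")
  expect_named(sig, c("Cp", "Lp"))

  # degenerate config: observed differences only
  tab0 <- sweep_comparison(cA, cB, metrics = "Cp", sweep = sweep,
                           n_perm = 0)
  expect_true(all(is.na(tab0$p)))
  expect_true(all(is.finite(tab0$observed_diff)))

  # identical cohorts: no significant densities for deterministic metrics
  tabI <- sweep_comparison(cA, cA, metrics = "Cp", sweep = sweep,
                           n_perm = 20, seed = 3)
  expect_false(any(tabI$significant))
})

test_that("density range formatting collapses contiguous runs", {
  expect_identical(format_density_ranges(numeric(0)), "")
  expect_identical(format_density_ranges(c(0.19, 0.20, 0.21)), "19%-21%")
  expect_identical(format_density_ranges(c(0.14, 0.15, 0.18)),
                   "14%-15%, 18%")
})
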
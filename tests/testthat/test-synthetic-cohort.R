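test_that("latent covariance handles the independence and complete cases", {
  cfg0 <- cohort_config(n_rois = 5L, group_sizes = c(A = 10L),
                        latent_k = 0L, seed = 1L)
  expect_equal(unname(build_latent_covariance(cfg0)), diag(5),
               ignore_attr = TRUE)

  cfg3 <- cohort_config(n_rois = 3L, group_sizes = c(A = 10L),
                        latent_k = 2L, latent_p = 0,
                        within_edge_correlation = 0.5, seed = 1L)
  C <- build_latent_covariance(cfg3)
  expect_equal(unname(C), matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3),
               ignore_attr = TRUE)
  expect_gt(min(eigen(C, symmetric = TRUE)$values), 0)
})

test_that("repaired ring-lattice latent covariance is positive definite", {
  cfg <- cohort_config(group_sizes = c(A = 10L), latent_k = 10L,
                       latent_p = 0.1, within_edge_correlation = 0.4,
                       seed = 42L)
  C <- suppressMessages(build_latent_covariance(cfg))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(unname(diag(C)), rep(1, 90))
  expect_equal(C, t(C))
})

test_that("identical configuration and seed reproduce the cohort exactly", {
  cfg <- tiny_config()
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$values, co2$values)
  expect_identical(co1$covariates, co2$covariates)
  expect_identical(co1$group, co2$group)
})

test_that("configured edge correlation is recovered in the sample", {
  # One latent pair at r = 0.6, no confounds and no global scale so the
  # raw Pearson correlation estimates the latent value directly.
  cfg <- cohort_config(n_rois = 4L, group_sizes = c(A = 500L),
                       latent_edges = cbind(1L, 2L),
                       within_edge_correlation = 0.6,
                       covariate_effects = list(age = 0, sex = 0,
                                                education = 0),
                       global_scale_sd = 0, seed = 7L)
  co <- simulate_group(cfg, "A")
  r <- cor(co$values[, 1], co$values[, 2])
  expect_lt(abs(r - 0.6), 0.08)

  # Identity latent covariance: off-diagonal sample correlations vanish.
  cfg0 <- cohort_config(n_rois = 15L, group_sizes = c(A = 500L),
                        latent_k = 0L,
                        covariate_effects = list(age = 0, sex = 0,
                                                 education = 0),
                        global_scale_sd = 0, seed = 8L)
  R <- cor(simulate_group(cfg0, "A")$values)
  expect_lt(mean(abs(R[upper.tri(R)])), 0.08)
})

test_that("covariate effects are recoverable by least squares", {
  cfg <- cohort_config(n_rois = 8L, group_sizes = c(A = 500L),
                       latent_k = 0L,
                       covariate_effects = list(age = -0.05, sex = 0.8,
                                                education = 0.1),
                       global_scale_sd = 0, seed = 9L)
  co <- simulate_group(cfg, "A")
  for (j in c(1L, 5L)) {
    fit <- summary(lm(co$values[, j] ~ age + sex + education,
                      data = co$covariates))$coefficients
    expect_lt(abs(fit["age", 1] - (-0.05)), 3 * fit["age", 2])
    expect_lt(abs(fit["sex", 1] - 0.8), 3 * fit["sex", 2])
    expect_lt(abs(fit["education", 1] - 0.1), 3 * fit["education", 2])
  }
})

test_that("cohort values are positive, finite, and labelled uniquely", {
  co <- simulate_cohort(brain_config(n_per_group = 10L))
  expect_true(all(co$values > 0))
  expect_true(all(is.finite(co$values)))
  expect_false(anyDuplicated(co$roi_labels) > 0)
  expect_identical(co$roi_labels, aal90_labels())
})

test_that("perturbation with attenuation 1 is the identity", {
  co <- simulate_cohort(tiny_config())
  out <- apply_perturbation(co, "focal", co$roi_labels[1:3], 1.0)
  expect_identical(out$values, co$values)
  # and the input is never modified
  out2 <- apply_perturbation(co, "focal", co$roi_labels[1:3], 0.2,
                             seed = 5L)
  expect_false(identical(out2$values, co$values))
  expect_true(all(out2$values[, 4:20] == co$values[, 4:20]))
})

test_that("perturbation argument errors are raised", {
  co <- simulate_cohort(tiny_config())
  expect_error(apply_perturbation(co, "focal", character(0), 0.5),
               "non-empty")
  expect_error(apply_perturbation(co, "focal", "NOPE", 0.5), "labels")
  expect_error(apply_perturbation(co, "focal", co$roi_labels[1], 1.7),
               "attenuation")
})

test_that("full focal decorrelation removes correlation with neighbors", {
  # four DMN-scale ROIs on a pure ring lattice (each latently tied to
  # its 10 nearest index neighbors); after attenuation-0 focal
  # perturbation their correlations with former neighbors collapse.
  # The perturbation divides out the estimated per-subject global
  # scale, whose accuracy needs the full-width ROI table, so the check
  # runs at the 90-ROI study scale.
  cfg <- cohort_config(group_sizes = c(A = 500L), latent_k = 10L,
                       latent_p = 0, within_edge_correlation = 0.4,
                       covariate_effects = list(age = 0, sex = 0,
                                                education = 0),
                       global_scale_sd = 0, seed = 11L)
  co <- suppressMessages(simulate_group(cfg, "A"))
  idx <- 40:43
  nbr <- setdiff(unique(unlist(lapply(idx, function(i) {
    ((i + c(-5:-1, 1:5) - 1L) %% 90L) + 1L
  }))), idx)
  before <- mean(abs(cor(co$values[, idx], co$values[, nbr])))
  expect_gt(before, 0.2)
  pert <- apply_perturbation(co, "focal", aal90_labels()[idx], 0,
                             seed = 3L)
  after <- mean(abs(cor(pert$values[, idx], pert$values[, nbr])))
  expect_lt(after, 0.1)
})

test_that("cohort CSV round-trips through the documented dialect", {
  co <- simulate_cohort(tiny_config(n_rois = 6L, n_per_group = 8L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  expect_identical(header[1:5],
                   c("subject_id", "group", "age", "sex", "education"))
  back <- read_cohort_csv(path)
  expect_equal(back$values, co$values, tolerance = 1e-12)
  expect_identical(back$group, co$group)
})

test_that("group sizes below the covariate floor are rejected", {
  expect_error(cohort_config(group_sizes = c(A = 5L)), "at least 6")
  expect_error(cohort_config(group_sizes = c(A = 10L),
                             within_edge_correlation = 1.2), "\\(0, 1\\)")
})
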
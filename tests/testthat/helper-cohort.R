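# Shared small cohort configurations for tests.

tiny_config <- function(n_rois = 20L, n_per_group = 30L,
                        groups = c("A", "B"), seed = 101L, ...) {
  sizes <- stats::setNames(rep(n_per_group, length(groups)), groups)
  cohort_config(n_rois = n_rois, group_sizes = sizes,
                latent_k = 4L, latent_p = 0.1,
                within_edge_correlation = 0.3, seed = seed, ...)
}

# Default-style 90-ROI config at reduced subject counts.
brain_config <- function(n_per_group = 60L, groups = c("CN", "MCI", "AD"),
                         seed = 202L, ...) {
  sizes <- stats::setNames(rep(n_per_group, length(groups)), groups)
  cohort_config(group_sizes = sizes, seed = seed, ...)
}
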
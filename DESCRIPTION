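Package: metabnet
Title: Graph-Theoretical Analysis of Brain Metabolic Covariance Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs group-level brain metabolic covariance networks from
    subjects-by-ROI tables of regional glucose metabolism, following the
    graph-theoretical connectomics workflow used in FDG-PET studies of
    aging and dementia: global normalization, partial correlation adjusted
    for age, sex and education, fixed-density binarization over a density
    sweep, small-world indices (gamma, lambda, sigma) against
    degree-preserving random references, betweenness-centrality hub
    detection, nonparametric label-permutation group comparison, and
    seed-based connectivity comparison via the Fisher r-to-z transform with
    false-discovery-rate control. Includes a synthetic cohort generator
    with a latent small-world covariance structure, linear confound
    effects, per-subject global scaling, and focal or diffuse
    hypometabolism perturbations, so the full pipeline is testable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    Matrix,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
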
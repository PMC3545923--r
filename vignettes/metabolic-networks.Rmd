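---
title: "Group-level metabolic covariance networks: methods and design"
author: "metabnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level metabolic covariance networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabnet)
```

## The problem

Resting FDG-PET measures regional cerebral glucose metabolism (rCMglc),
a proxy for synaptic activity. Across subjects, regions that work
together tend to covary metabolically, so an interregional correlation
matrix computed over a group of subjects can be read as that group's
*metabolic covariance network*: nodes are atlas regions, edges are
strong interregional correlations. Graph-theoretical summaries of such
networks — local clustering, path length, small-world indices, hub
centrality — are widely used to characterize how network organization
changes in mild cognitive impairment (MCI) and Alzheimer-type dementia
(AD) relative to cognitively normal (CN) aging.

metabnet implements that analysis end to end for subjects × ROI tables
using the 90-region AAL parcellation (45 regions per hemisphere,
cerebellum excluded), plus a synthetic cohort generator so every stage
is testable without imaging data. The design is *group-level by
construction*: one network per group, with inference by label
permutation, not per-subject networks.

## From a cohort table to a binary graph

**Global normalization.** Each subject's 90 ROI values are divided by
that subject's mean over the ROIs (`global_normalize()`), the ROI-level
analogue of whole-brain normalization of rCMglc. Every subject then has
row mean exactly 1; per-subject global scale factors (scanner
sensitivity, global metabolism) cancel exactly when they are
multiplicative.

**Covariate-adjusted correlation.** `partial_correlation_matrix()`
regresses every ROI column on an intercept plus age, sex and education
and correlates the residuals — the partial correlation of every ROI
pair controlling for those three confounds. Degenerate inputs are
handled explicitly: zero-variance covariates are dropped with a warning
(when all covariates are constant the result *is* the Pearson matrix),
rank-deficient covariate sets are reduced, and constant ROI columns get
coefficient 0 with a warning rather than NaN. The diagonal is zeroed by
convention.

**Fixed-density binarization.** `binarize_fixed_density()` ranks the
N(N−1)/2 distinct coefficients by signed value and keeps the top
`K = round(D · N(N−1)/2)` as edges (rounding half away from zero).
Fixing the density — rather than a correlation cutoff — guarantees that
the graphs compared between groups have *identical* edge counts, so
group differences in graph metrics reflect topology, not edge count.
Three numerical choices are deliberate:

* **Signed, not absolute, ranking.** Metabolic covariance analyses
  conventionally interpret positive covariance; an `absolute = TRUE`
  switch is provided for sensitivity analyses.
* **Ties** are broken deterministically by lower ROI index, then lower
  partner index, so binarization is exactly reproducible.
* **Rounding** is half-away-from-zero, making K exact and monotone in D
  (at N = 90, D = 0.15 gives K = 601).

`binarize_r_threshold()` provides the correlation-cutoff alternative
(edge where r > r_min, nested decreasing in r_min) used to check that
fixed-density results are not an artifact of the thresholding rule.

**The density sweep.** There is no gold-standard single density, so all
group analyses repeat over 6 % ≤ D ≤ 40 % in 1 % steps — 35 levels
(`density_sweep()`). Below ~6 % a 90-node graph fragments badly; above
~40 % it approaches a clique and small-world structure is no longer
estimable.

**The fixed density for nodal metrics.** Nodal betweenness is reported
at one density: the lowest sweep density at which the graph's largest
connected component spans all 90 ROIs
(`lowest_full_connection_density()`) — the sparsest graph in which
every region participates, minimizing false-positive paths. The
pipeline falls back to 15 % with a warning if no sweep density fully
connects the graph.

## Graph metrics

All metrics are for simple undirected, unweighted graphs
(`binary_graph`); weighted or directed generalizations are out of
scope. The primitive computations (local clustering, geodesics,
betweenness, components, degree-preserving rewiring) are delegated to
igraph; the test suite cross-checks them against independent
brute-force oracles (exhaustive path enumeration in plain R) on
hundreds of small graphs.

* **Clustering** `C_i = 2 e_i / (k_i (k_i − 1))`, the fraction of a
  node's neighbor pairs that are themselves connected; `C_p` is the
  mean over *all* nodes, with degree < 2 nodes contributing 0 (they are
  not excluded from the average).
* **Characteristic path length** `L_p` is the mean geodesic length over
  node pairs. At densities of 6–14 % full connection is not guaranteed
  and some pairs have no path; the package averages over *connected
  pairs only* (the least-assumptive finite convention), reports the
  number of excluded pairs as an attribute, and offers a
  largest-component-only alternative via `lp_convention`.
* **Betweenness** `B_i` is Freeman betweenness: shortest paths between
  other node pairs through node *i*, fractional credit over multiple
  geodesics, endpoints excluded. Normalized betweenness
  `b_i = B_i / mean(B)` averages to 1 by construction; nodes with
  `b_i > 1.5` (configurable) are called hubs. When mean betweenness is
  0 (e.g. a complete graph), `b` is undefined and flagged rather than
  silently zeroed.

## Small-world indices against degree-matched nulls

A network is small-world when it clusters like a lattice but has the
short paths of a random graph. `small_world_indices()` compares the
observed graph with random references that preserve the exact degree
sequence, generated by repeated double-edge swaps
(`rewire_preserving_degree()`; a–b, c–d → a–d, c–b when no self-loop or
duplicate would result). The indices are

γ = C_p / C_p^rand,  λ = L_p / L_p^rand,  σ = γ / λ,

with C_p^rand and L_p^rand the means over `n_random` references
(default 1000; 100 is ample for desk-scale checks) and σ > 1 the
small-world criterion. Three conventions matter and are deliberate:

* each reference uses a swap-attempt budget of 10·|E| (the standard
  mixing heuristic; only the reference *count* is a study-level
  parameter);
* references are *not* forced to stay connected — connectivity
  enforcement biases the reference ensemble — and L_p of references
  uses the same connected-pairs convention as the real graph;
* references are regenerated per group and per density, under a seed
  recorded in the result for exact reruns. For tree-like graphs
  C_p^rand can be 0, in which case γ and σ are NA and flagged.

## Permutation inference over the sweep

Between-group differences in C_p, L_p, σ and nodal b are tested
nonparametrically (`permutation_test()`, `sweep_comparison()`): pool
the subjects of the two groups, reassign them at random to
pseudo-groups of the original sizes, and rebuild *everything* —
normalization is per-subject, covariates travel with their subjects,
and the partial-correlation matrix, binarization and metric are
recomputed per pseudo-group. The observed difference is referred to the
permutation null (default 5000 repetitions; the critical value is the
null's 95th percentile in the tested direction) with the add-one
estimator p = (1 + #{null ≥ observed}) / (n_perm + 1), which cannot
return 0 and matches the percentile criterion asymptotically.

**Direction of the one-tailed test.** The default tests a direction
fixed a priori (`alternative = "greater"`: order the groups so the
hypothesized-larger one comes first, as when testing CN > patients).
This was a genuinely open design choice; the deciding argument is
calibration. Taking the tail from the *sign of the observed difference*
(`alternative = "observed"`, also provided) inspects the data twice:
under a symmetric null either extreme tail rejects, and the realized
type-I error is ~2× nominal. The package's calibration test simulates
the entire pipeline under the null generator (200 datasets × 200
permutations, 40 + 40 subjects) and verifies that the default test
rejects at the nominal 5 % rate; with the observed-direction rule the
same simulation rejects at ~10 %, which is why that rule is not the
default.

The sweep applies the test at every density *without*
multiple-comparison adjustment: the sweep is read as a trend (contiguous
runs of significant densities, formatted by `format_density_ranges()`),
not as 35 independent hypotheses. Inside the permutation loop σ uses a
reduced reference count (`n_random_perm`, default 100) for tractability;
it can be raised to the full 1000 at ~10× cost.

Three-group studies are handled pairwise (CN–MCI, CN–AD, MCI–AD), and
any relabelling (e.g. severity subgroups) is just another two-group run.

## Seed-based connectivity comparison

For hub regions of interest (defaults: left triangular inferior frontal
gyrus `IFGtriang_L` and left precuneus `PCUN_L`), `seed_rmap()` computes
the Pearson correlation of the seed ROI with each of the other 89 ROIs
per group — an ROI-level R-map. Group maps are compared on the Fisher
z scale, z = ½·ln((1+r)/(1−r)) (natural log), with the standard
two-sample statistic for independent correlations

Z = (z₁ − z₂) / √(1/(n₁−3) + 1/(n₂−3)),

two-sided normal p, and Benjamini–Hochberg FDR control at q = 0.05 over
the 89 non-seed ROIs. This is an explicit ROI-level adaptation of a
voxel-level procedure: the package's data model is the ROI table, so
voxelwise maps and cluster-extent corrections are out of scope. An
optional positive-correlation mask (`positive_only = TRUE`, off by
default) restricts the FDR family to ROIs positively coupled to the
seed in both groups, since masking rules at ROI level are an
interpretation rather than a fixed convention.

## The synthetic cohort generator

`simulate_cohort()` exists so the pipeline's statistical behavior can
be verified against known ground truth. Its model is the simplest one
for which partial correlation is the correct estimand:

1. **Latent structure.** A Watts–Strogatz ring lattice over the 90 ROIs
   (k = 10 neighbors, rewiring probability 0.1 by default) defines
   which ROI pairs covary; the latent correlation matrix has
   `within_edge_correlation` (default 0.4) on edges and is repaired to
   the nearest positive-definite correlation matrix when the raw
   construction is indefinite (the repair is reported and shrinks edge
   correlations somewhat). This gives group networks genuine
   small-world structure — high clustering from the lattice, short
   paths from the rewired shortcuts.
2. **Subjects.** Each subject is a multivariate normal draw with SD
   `noise_sd` (default 2) around a baseline of 30 (the scale of
   cortical rCMglc in µmol/100 g/min), plus linear age, sex and
   education effects (defaults −0.05/yr, 0.8, 0.1/yr on that scale;
   age ~ U(55, 85), sex ~ Bernoulli(0.5) coded 0/1, education
   ~ U(6, 20) yr), times a per-subject log-normal global scale
   (SD 0.1, ~10 % spread) that global normalization must remove.
   Positivity is enforced, if ever needed, by a constant offset of at
   least five noise SDs — never by truncation, which would distort
   correlations. Identical seeds reproduce cohorts bit for bit.
3. **Disease-like perturbations.** `apply_perturbation()` attenuates
   ROI means (hypometabolism) and mixes subject-level fluctuations with
   fresh noise (decoupling) at mixing weight w, leaving variance
   unchanged; a perturbed ROI's correlations scale by w. Two modes
   encode the qualitative clinical contrast: **focal** applies
   w = attenuation to a small set (default: the 12-ROI default-mode
   core — posterior cingulate, precuneus, angular, parahippocampal,
   hippocampal and medial orbitofrontal regions), **diffuse** applies
   the milder w = (1 + attenuation)/2 over a broader set (default 30
   ROIs adding lateral temporal, inferior frontal, insular and parietal
   regions). The emulated MCI-like condition is *severe focal*
   decoupling (attenuation 0) and the AD-like condition *mild diffuse*
   perturbation (attenuation 0.6): pilot simulation of the generator
   confirmed that this severity inversion — not the set sizes alone —
   is what reproduces the clinically reported ordering of group
   clustering (MCI-like < AD-like < CN-like) at matched density.

Two generator subtleties found during design are worth recording.
First, the perturbation operates on the *subject-scale-adjusted*
signal: each subject's global factor is estimated from its whole-brain
mean, divided out, the mixing applied, and the factor restored. Fresh
noise injected on the raw scale instead would survive global
normalization as a shared 1/scale component and spuriously correlate
the perturbed ROIs with each other. (A corollary: the scale estimate
needs the full-width ROI table, so perturbation behavior is specified
at the 90-ROI scale, not in toy 6-ROI configurations.) Second,
fixed-density thresholding redistributes displaced edges: decoupling
lowers group clustering in the study regime, where the retained edge
count (601 at 15 %) exceeds the latent edge count (450), but in small
toy graphs where K is *below* the latent edge count the displaced edges
land on the intact lattice and clustering can even rise.

**What the generator does not emulate** — and hence what passing tests
do and do not show: no PET physics (no voxels, partial-volume effects,
scanner noise or spatial smoothing), Gaussian rather than heavy-tailed
regional noise, linear confound effects only, and a single latent
structure per cohort rather than subject-level heterogeneity. Tests on
synthetic cohorts validate the *statistical machinery* (estimands,
calibration, direction of effects); they cannot validate claims about
real FDG-PET data.

## Problem sizes used by the test suite

The suite verifies the study-scale contracts at reduced but adequate
sizes, chosen once: Monte-Carlo recovery checks at n = 500 subjects;
calibration of the permutation test over 200 simulated datasets × 200
permutations (40 + 40 subjects, C_p at 15 %); the severity-ordering
check over 10 cohorts of 100 subjects; small-world detection on a
150-subject cohort with 100 random references; oracle equivalence on
200 random connected graphs of ≤ 7 nodes. The full-budget settings
(1000 references, 5000 permutations) remain the documented defaults of
the user-facing functions.

## Known limitations

* Group-level design: no per-subject network statistics, so effect
  sizes are at the group-network level and inference rests entirely on
  the permutation scheme.
* The fixed-density rule admits weak (possibly spurious) correlations
  as edges in groups with globally weakened covariance; the r-threshold
  alternative is provided as a check.
* L_p's connected-pairs convention makes sparse-density L_p values
  dependent on the exclusion rule; comparisons at the same density are
  unaffected, absolute values across conventions are not comparable.
* nearPD repair of the latent correlation matrix shrinks configured
  edge correlations, so `within_edge_correlation` is a target only
  where the raw construction is already positive definite.
* The generator's perturbation magnitudes are free parameters encoding
  a qualitative clinical contrast, not estimates from any dataset.
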
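#' Fisher r-to-z transform
#'
#' The variance-stabilizing transform `z = 0.5 * ln((1 + r) / (1 - r))`
#' (natural logarithm), strictly increasing and odd. Its inverse is
#' [inverse_fisher_z()] (`tanh`).
#'
#' @param r Correlation coefficient(s), `|r| < 1`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z requires |r| < 1")
  0.5 * log((1 + r) / (1 - r))
}

#' @rdname fisher_z
#' @param z Fisher-transformed value(s).
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Seed-based correlation map over ROIs
#'
#' Pearson correlation, across subjects, between the seed ROI's values
#' and every other ROI: the ROI-level analogue of a seed R-map. The
#' cohort should be globally normalized first (see [global_normalize()]).
#'
#' @param cohort A [roi_cohort()].
#' @param seed_roi Seed ROI label.
#' @return Named numeric vector of correlations over the other ROIs (the
#'   seed itself is excluded).
#' @export
seed_rmap <- function(cohort, seed_roi) {
  stopifnot(inherits(cohort, "roi_cohort"))
  j <- match(seed_roi, cohort$roi_labels)
  if (is.na(j)) stop("unknown seed ROI '", seed_roi, "'")
  s <- cohort$values[, j]
  if (stats::sd(s) == 0) stop("seed ROI '", seed_roi, "' is constant")
  r <- drop(stats::cor(s, cohort$values[, -j, drop = FALSE]))
  names(r) <- cohort$roi_labels[-j]
  r
}

#' Two-sample Z test for comparing independent correlations
#'
#' Compares correlation coefficients from two independent groups on the
#' Fisher z scale:
#' `Z = (z1 - z2) / sqrt(1/(n1 - 3) + 1/(n2 - 3))`,
#' referred to the standard normal (two-sided p). Antisymmetric under
#' swapping the groups.
#'
#' @param r1,r2 Correlations (`|r| < 1`), vectorized.
#' @param n1,n2 Group sizes (each > 3).
#' @return List with `z_stat` and `p` (same length as `r1`).
#' @export
two_sample_z <- function(r1, n1, r2, n2) {
  if (n1 <= 3L || n2 <= 3L) stop("group sizes must exceed 3")
  z <- (fisher_z(r1) - fisher_z(r2)) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z_stat = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Step-up false-discovery-rate control at level `q`: returns a logical
#' mask of the p-values that survive.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical vector (empty input gives an empty mask).
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Between-group seed connectivity comparison
#'
#' Builds each group's seed R-map ([seed_rmap()] after global
#' normalization), compares the per-ROI correlations between groups with
#' the Fisher r-to-z two-sample Z statistic, and controls the false
#' discovery rate over the non-seed ROIs at level `q`. With
#' `positive_only = TRUE`, only ROIs positively correlated with the seed
#' in both groups enter the FDR family (others get `NA`).
#'
#' @param cohortA,cohortB [roi_cohort()] objects sharing ROI labels.
#' @param seed_roi Seed ROI label.
#' @param q FDR level (default 0.05).
#' @param positive_only Restrict the comparison to ROIs with positive
#'   seed correlation in both groups (default `FALSE`).
#' @return Object of class `seed_comparison`: a data frame with columns
#'   `roi`, `r_group1`, `r_group2`, `z_stat`, `p`, `q_significant`, plus
#'   attributes `seed_roi`, `n_by_group`, `significant_rois`.
#' @export
seed_group_comparison <- function(cohortA, cohortB, seed_roi, q = 0.05,
                                  positive_only = FALSE) {
  stopifnot(inherits(cohortA, "roi_cohort"), inherits(cohortB, "roi_cohort"))
  if (!identical(cohortA$roi_labels, cohortB$roi_labels))
    stop("cohorts must share the same ROI labels in the same order")
  rA <- seed_rmap(global_normalize(cohortA), seed_roi)
  rB <- seed_rmap(global_normalize(cohortB), seed_roi)
  nA <- nrow(cohortA$values)
  nB <- nrow(cohortB$values)
  ts <- two_sample_z(rA, nA, rB, nB)
  sig <- rep(NA, length(rA))
  family <- if (positive_only) which(rA > 0 & rB > 0) else seq_along(rA)
  sig[family] <- fdr_adjust(ts$p[family], q)
  out <- data.frame(roi = names(rA), r_group1 = unname(rA),
                    r_group2 = unname(rB), z_stat = unname(ts$z_stat),
                    p = unname(ts$p), q_significant = sig)
  attr(out, "seed_roi") <- seed_roi
  attr(out, "n_by_group") <- c(nA, nB)
  attr(out, "significant_rois") <- out$roi[which(out$q_significant)]
  class(out) <- c("seed_comparison", class(out))
  out
}
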
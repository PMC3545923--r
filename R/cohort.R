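#' Configuration for a synthetic metabolic cohort
#'
#' Describes a multi-group cohort of subjects with per-ROI metabolic
#' values (in the role of regional cerebral glucose metabolism, rCMglc)
#' drawn from a multivariate normal whose correlation structure is
#' elevated on the edges of a latent small-world graph, plus linear
#' age/sex/education confound effects and a per-subject multiplicative
#' global scale.
#'
#' @param n_rois Number of ROIs (default 90).
#' @param roi_labels ROI names; defaults to [aal90_labels()] when
#'   `n_rois == 90`, otherwise `ROI1..ROIn`.
#' @param group_sizes Named integer vector of subjects per group. Defaults
#'   to the cohort sizes typical of a three-group dementia study
#'   (`CN = 94, MCI = 183, AD = 216`). Every group must have at least
#'   `3 + 3` subjects so partial correlation over three covariates is
#'   defined with headroom.
#' @param latent_k Ring-lattice neighbor count (even) of the latent
#'   Watts-Strogatz graph; `0` gives an empty latent graph (independent
#'   ROIs).
#' @param latent_p Rewiring probability of the latent graph in `[0, 1]`.
#' @param latent_edges Optional explicit two-column matrix of ROI index
#'   pairs; overrides the ring-lattice spec when supplied.
#' @param within_edge_correlation Target correlation on latent edges,
#'   in (0, 1).
#' @param baseline_mean Baseline metabolic value per ROI (scalar or
#'   length-`n_rois`), arbitrary positive units; default 30 (the scale of
#'   cortical rCMglc in umol/100 g/min).
#' @param noise_sd Per-ROI noise standard deviation on the same scale
#'   (default 2). The latent covariance is `noise_sd^2` times the latent
#'   correlation matrix.
#' @param covariate_effects Named list with elements `age`, `sex`,
#'   `education`: linear coefficients per ROI (scalar recycled or
#'   length-`n_rois`).
#' @param age_range,education_range Uniform sampling ranges for age
#'   (years) and education (years). Sex is coded 0/1, drawn with
#'   probability 0.5.
#' @param global_scale_sd SD of the per-subject log-normal multiplicative
#'   global scale (default 0.1, i.e. ~10% spread).
#' @param perturbation Named list of per-group perturbation specs, each a
#'   list with `mode` (`"focal"` or `"diffuse"`), `roi_set` (labels) and
#'   `attenuation` in `[0, 1]` (1 = untouched, 0 = fully decoupled);
#'   groups not named are left unperturbed.
#' @param seed Integer master seed for the cohort.
#' @return An object of class `cohort_config`.
#' @seealso [simulate_cohort()], [build_latent_covariance()]
#' @export
cohort_config <- function(n_rois = 90L,
                          roi_labels = NULL,
                          group_sizes = c(CN = 94L, MCI = 183L, AD = 216L),
                          latent_k = 10L,
                          latent_p = 0.1,
                          latent_edges = NULL,
                          within_edge_correlation = 0.4,
                          baseline_mean = 30,
                          noise_sd = 2,
                          covariate_effects = list(age = -0.05, sex = 0.8,
                                                   education = 0.1),
                          age_range = c(55, 85),
                          education_range = c(6, 20),
                          global_scale_sd = 0.1,
                          perturbation = list(),
                          seed = 1L) {
  n_rois <- as.integer(n_rois)
  if (is.null(roi_labels)) {
    roi_labels <- if (n_rois == 90L) aal90_labels() else
      paste0("ROI", seq_len(n_rois))
  }
  stopifnot(length(roi_labels) == n_rois, !anyDuplicated(roi_labels))
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be a named vector")
  if (any(group_sizes < 6L))
    stop("every group needs at least 6 subjects ",
         "(number of covariates + 3) for partial correlation")
  if (!(within_edge_correlation > 0 && within_edge_correlation < 1))
    stop("within_edge_correlation must lie in (0, 1)")
  if (is.null(latent_edges)) {
    latent_k <- as.integer(latent_k)
    if (latent_k < 0L || latent_k %% 2L != 0L)
      stop("latent_k must be a non-negative even integer")
    if (latent_p < 0 || latent_p > 1) stop("latent_p must be in [0, 1]")
  } else {
    latent_edges <- as.matrix(latent_edges)
    stopifnot(ncol(latent_edges) == 2L,
              all(latent_edges >= 1L), all(latent_edges <= n_rois),
              all(latent_edges[, 1L] != latent_edges[, 2L]))
  }
  for (p in perturbation) {
    stopifnot(p$mode %in% c("none", "focal", "diffuse"))
    if (p$mode != "none") {
      if (length(p$roi_set) == 0L)
        stop("perturbation roi_set must be non-empty")
      if (!all(p$roi_set %in% roi_labels))
        stop("perturbation roi_set contains unknown ROI labels")
      if (p$attenuation < 0 || p$attenuation > 1)
        stop("attenuation must be in [0, 1]")
    }
  }
  stopifnot(noise_sd > 0, all(baseline_mean > 0), global_scale_sd >= 0)
  ce <- lapply(covariate_effects[c("age", "sex", "education")], function(b) {
    if (is.null(b)) b <- 0
    rep_len(b, n_rois)
  })
  structure(list(
    n_rois = n_rois, roi_labels = roi_labels,
    group_sizes = group_sizes,
    latent_k = latent_k, latent_p = latent_p, latent_edges = latent_edges,
    within_edge_correlation = within_edge_correlation,
    baseline_mean = rep_len(baseline_mean, n_rois),
    noise_sd = noise_sd,
    covariate_effects = ce,
    age_range = age_range, education_range = education_range,
    global_scale_sd = global_scale_sd,
    perturbation = perturbation,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Latent ROI-ROI correlation matrix of a cohort configuration
#'
#' Builds the latent graph (a Watts-Strogatz ring lattice with `latent_k`
#' neighbors rewired with probability `latent_p`, or the explicit
#' `latent_edges`), places `within_edge_correlation` on its edges and 1 on
#' the diagonal, and repairs the result to the nearest positive-definite
#' correlation matrix when needed (repair is recorded in the `"repaired"`
#' attribute and reported via a message).
#'
#' @param config A [cohort_config()].
#' @return `n_rois x n_rois` correlation matrix with attributes
#'   `latent_edges` (two-column index matrix) and `repaired` (logical).
#' @export
build_latent_covariance <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_rois
  if (!is.null(config$latent_edges)) {
    edges <- config$latent_edges
  } else if (config$latent_k == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    g <- withr::with_seed(config$seed + 104729L,
      igraph::sample_smallworld(1L, n, config$latent_k / 2L,
                                config$latent_p))
    g <- igraph::simplify(g)
    edges <- igraph::as_edgelist(g, names = FALSE)
  }
  C <- diag(n)
  if (nrow(edges) > 0L) {
    rho <- config$within_edge_correlation
    C[edges] <- rho
    C[edges[, 2:1, drop = FALSE]] <- rho
  }
  repaired <- FALSE
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-8) {
    np <- tryCatch(
      Matrix::nearPD(C, corr = TRUE, keepDiag = TRUE, maxit = 200L),
      error = function(e)
        stop("latent covariance is not repairable to positive definite ",
             "(smallest eigenvalue ", signif(ev_min, 4), ")"))
    C <- as.matrix(np$mat)
    C <- (C + t(C)) / 2
    repaired <- TRUE
    ev2 <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev2 <= 0)
      stop("latent covariance is not repairable to positive definite ",
           "(smallest eigenvalue ", signif(ev2, 4), " after repair)")
    message("latent correlation matrix repaired to nearest positive ",
            "definite (smallest eigenvalue was ", signif(ev_min, 4), ")")
  }
  dimnames(C) <- list(config$roi_labels, config$roi_labels)
  attr(C, "latent_edges") <- edges
  attr(C, "repaired") <- repaired
  C
}

#' Construct a subjects-by-ROI metabolic cohort object
#'
#' @param values Numeric subjects x ROI matrix of positive metabolic
#'   values.
#' @param covariates Data frame with numeric columns `age`, `sex` (0/1)
#'   and `education`, one row per subject.
#' @param group Character vector of group labels, one per subject.
#' @param roi_labels ROI names; defaults to `colnames(values)`.
#' @return An object of class `roi_cohort` with fields `values`,
#'   `covariates`, `group`, `roi_labels`.
#' @export
roi_cohort <- function(values, covariates, group, roi_labels = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(roi_labels)) stop("roi_labels required")
  stopifnot(length(roi_labels) == ncol(values),
            !anyDuplicated(roi_labels),
            nrow(values) == nrow(covariates),
            nrow(values) == length(group),
            all(c("age", "sex", "education") %in% names(covariates)))
  if (anyNA(values) || any(!is.finite(values)))
    stop("metabolic values must be finite and non-missing")
  if (any(values <= 0)) stop("all metabolic values must be positive")
  if (anyNA(covariates) || any(!vapply(covariates[c("age", "sex", "education")],
                                       function(x) all(is.finite(x)), TRUE)))
    stop("covariates must be finite")
  colnames(values) <- roi_labels
  structure(list(values = values,
                 covariates = as.data.frame(covariates)[, c("age", "sex",
                                                            "education")],
                 group = as.character(group),
                 roi_labels = roi_labels),
            class = "roi_cohort")
}

#' @export
print.roi_cohort <- function(x, ...) {
  cat("<roi_cohort> ", nrow(x$values), " subjects x ", length(x$roi_labels),
      " ROIs\n", sep = "")
  tab <- table(x$group)
  cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of subjects / subset by group
#'
#' @param cohort A [roi_cohort()].
#' @param group Group label to keep.
#' @return `subset_group()` returns the sub-cohort of one group.
#' @export
subset_group <- function(cohort, group) {
  stopifnot(inherits(cohort, "roi_cohort"))
  keep <- cohort$group == group
  if (!any(keep)) stop("no subjects in group '", group, "'")
  roi_cohort(cohort$values[keep, , drop = FALSE],
             cohort$covariates[keep, , drop = FALSE],
             cohort$group[keep], cohort$roi_labels)
}

#' Simulate one group of a synthetic cohort
#'
#' Draws `group_sizes[group]` subjects from a multivariate normal with the
#' latent covariance (`noise_sd^2` times [build_latent_covariance()]),
#' adds the ROI baselines and linear age/sex/education effects, applies a
#' per-subject log-normal global scale, and -- should any value be
#' non-positive -- shifts all values up by a constant offset of at least
#' five noise SDs (a shift rather than truncation, which would distort
#' correlations). The same configuration and seed always reproduce the
#' same cohort. Any perturbation configured for the group is NOT applied
#' here; see [simulate_cohort()] and [apply_perturbation()].
#'
#' @param config A [cohort_config()].
#' @param group Group name (must be in `names(config$group_sizes)`).
#' @param latent Optional precomputed latent correlation matrix (to avoid
#'   rebuilding it per group).
#' @return A [roi_cohort()] with all subjects labelled `group`.
#' @export
simulate_group <- function(config, group, latent = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  gi <- match(group, names(config$group_sizes))
  if (is.na(gi)) stop("unknown group '", group, "'")
  n <- as.integer(config$group_sizes[[gi]])
  p <- config$n_rois
  if (is.null(latent)) latent <- build_latent_covariance(config)
  Sigma <- latent * config$noise_sd^2
  seed_g <- config$seed + 7919L * gi
  sim <- withr::with_seed(seed_g, {
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- stats::rbinom(n, 1L, 0.5)
    edu <- stats::runif(n, config$education_range[1],
                        config$education_range[2])
    E <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma)
    s <- exp(stats::rnorm(n, 0, config$global_scale_sd))
    list(age = age, sex = sex, edu = edu, E = E, s = s)
  })
  B <- rbind(config$covariate_effects$age,
             config$covariate_effects$sex,
             config$covariate_effects$education)
  covm <- cbind(sim$age, sim$sex, sim$edu)
  raw <- matrix(config$baseline_mean, n, p, byrow = TRUE) +
    covm %*% B + sim$E
  if (min(raw) <= 0) {
    offset <- 5 * config$noise_sd - min(raw)
    raw <- raw + offset
    message("group '", group, "': values shifted by constant offset ",
            signif(offset, 4), " to enforce positivity")
  }
  values <- raw * sim$s
  if (any(values <= 0))
    stop("non-positive metabolic values remain after positivity shift")
  colnames(values) <- config$roi_labels
  roi_cohort(values,
             data.frame(age = sim$age, sex = sim$sex, education = sim$edu),
             rep(group, n), config$roi_labels)
}

#' Apply a focal or diffuse hypometabolism / decoupling perturbation
#'
#' Emulates disease-like alteration of a cohort: each ROI in `roi_set` has
#' its mean attenuated (hypometabolism) and its subject-level fluctuations
#' mixed with fresh independent noise (decoupling from former latent
#' neighbors), leaving per-ROI variance unchanged. With mixing weight `w`,
#' a perturbed ROI's correlation with an untouched ROI scales by `w`.
#' Focal mode uses `w = attenuation` on a small set; diffuse mode uses the
#' milder `w = (1 + attenuation)/2` over a broader set. Means are scaled
#' by `0.75 + 0.25*attenuation` (focal) or `0.9 + 0.1*attenuation`
#' (diffuse). `attenuation = 1` returns the input unchanged. The input
#' cohort is never modified.
#'
#' @param cohort A [roi_cohort()].
#' @param mode `"none"`, `"focal"` or `"diffuse"`.
#' @param roi_set ROI labels to perturb (subset of `cohort$roi_labels`);
#'   required unless `mode = "none"`.
#' @param attenuation Value in `[0, 1]`: 1 leaves the cohort untouched, 0
#'   is maximal perturbation.
#' @param seed Integer seed for the fresh decoupling noise.
#' @return A new [roi_cohort()].
#' @export
apply_perturbation <- function(cohort, mode = c("none", "focal", "diffuse"),
                               roi_set = NULL, attenuation = 0.5,
                               seed = 1L) {
  stopifnot(inherits(cohort, "roi_cohort"))
  mode <- match.arg(mode)
  if (mode == "none") return(cohort)
  if (length(roi_set) == 0L)
    stop("roi_set must be non-empty for mode '", mode, "'")
  if (!all(roi_set %in% cohort$roi_labels))
    stop("roi_set contains labels not in the cohort")
  if (attenuation < 0 || attenuation > 1)
    stop("attenuation must be in [0, 1]")
  if (attenuation == 1) return(cohort)
  w <- if (mode == "focal") attenuation else (1 + attenuation) / 2
  mean_scale <- if (mode == "focal") 0.75 + 0.25 * attenuation else
    0.9 + 0.1 * attenuation
  values <- cohort$values
  n <- nrow(values)
  idx <- match(roi_set, cohort$roi_labels)
  eps <- withr::with_seed(seed,
    matrix(stats::rnorm(n * length(idx)), n, length(idx)))
  # The disease process scales regional metabolism underneath the
  # subject's global scale, so perturb the scale-adjusted signal:
  # estimate each subject's global factor from its whole-brain mean,
  # divide it out, mix, and restore it. Fresh noise injected on the raw
  # scale instead would survive global normalization as a shared 1/scale
  # component and spuriously correlate the perturbed ROIs.
  s_hat <- rowMeans(values) / mean(values)
  for (k in seq_along(idx)) {
    j <- idx[k]
    u <- values[, j] / s_hat
    m <- mean(u)
    sdev <- stats::sd(u)
    values[, j] <- s_hat * (m * mean_scale + w * (u - m) +
                              sqrt(1 - w^2) * sdev * eps[, k])
  }
  if (any(values <= 0))
    stop("perturbation produced non-positive metabolic values")
  roi_cohort(values, cohort$covariates, cohort$group, cohort$roi_labels)
}

#' Simulate a full multi-group cohort
#'
#' Simulates every group of the configuration with [simulate_group()] and
#' applies each group's configured perturbation (if any) with
#' [apply_perturbation()], using seeds derived from the master seed so the
#' whole cohort is reproducible.
#'
#' @param config A [cohort_config()].
#' @return A [roi_cohort()] containing all groups.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  latent <- build_latent_covariance(config)
  parts <- lapply(seq_along(config$group_sizes), function(gi) {
    g <- names(config$group_sizes)[gi]
    co <- simulate_group(config, g, latent = latent)
    pert <- config$perturbation[[g]]
    if (!is.null(pert) && pert$mode != "none") {
      co <- apply_perturbation(co, pert$mode, pert$roi_set,
                               pert$attenuation,
                               seed = config$seed + 7919L * gi + 13L)
    }
    co
  })
  roi_cohort(do.call(rbind, lapply(parts, `[[`, "values")),
             do.call(rbind, lapply(parts, `[[`, "covariates")),
             unlist(lapply(parts, `[[`, "group")),
             config$roi_labels)
}

#' Read / write cohort CSV
#'
#' The cohort CSV dialect has a header
#' `subject_id,group,age,sex,education,<ROI labels...>` and one row per
#' subject.
#'
#' @param cohort A [roi_cohort()].
#' @param path File path.
#' @return `read_cohort_csv()` returns a [roi_cohort()];
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "roi_cohort"))
  df <- data.frame(subject_id = sprintf("S%04d", seq_len(nrow(cohort$values))),
                   group = cohort$group,
                   cohort$covariates,
                   cohort$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("subject_id", "group", "age", "sex", "education")
  if (!all(meta %in% names(df)))
    stop("cohort CSV must have columns ", paste(meta, collapse = ", "))
  rois <- setdiff(names(df), meta)
  roi_cohort(as.matrix(df[, rois, drop = FALSE]),
             df[, c("age", "sex", "education")],
             df$group, rois)
}
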
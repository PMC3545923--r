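#' Pipeline run configuration
#'
#' Collects everything needed for an end-to-end run: the cohort source
#' (a [cohort_config()] to simulate, or a cohort CSV path), the density
#' sweep, the fixed-density rule for nodal metrics, the null-model and
#' permutation budgets, the hub threshold, the seed ROIs for the
#' connectivity comparison, and a master seed from which all
#' stage-specific seeds are derived.
#'
#' @param cohort A [cohort_config()], a [roi_cohort()], or a path to a
#'   cohort CSV.
#' @param sweep A [density_sweep()].
#' @param fixed_density `"auto"` (lowest density fully connecting the
#'   reference group's graph, falling back to 0.15 with a warning if none
#'   does) or an explicit fraction.
#' @param n_random Random references for sigma outside the permutation
#'   loop (study default 1000).
#' @param n_random_perm Random references for sigma inside the
#'   permutation loop (default 100; raise to `n_random` to match the
#'   full-budget convention at much higher cost).
#' @param n_perm Permutations per comparison (study default 5000).
#' @param hub_threshold Hub cutoff on normalized betweenness (default 1.5).
#' @param seed_rois Seed ROI labels for the seed connectivity stage.
#' @param sweep_metrics Metrics compared across the sweep.
#' @param seed Master integer seed.
#' @param out_dir Output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort,
                       sweep = density_sweep(),
                       fixed_density = "auto",
                       n_random = 1000L,
                       n_random_perm = 100L,
                       n_perm = 5000L,
                       hub_threshold = 1.5,
                       seed_rois = c("IFGtriang_L", "PCUN_L"),
                       sweep_metrics = c("Cp", "Lp", "sigma"),
                       seed = 1L,
                       out_dir = "metabnet-run") {
  stopifnot(inherits(sweep, "density_sweep"),
            identical(fixed_density, "auto") ||
              (is.numeric(fixed_density) && fixed_density > 0 &&
                 fixed_density < 1),
            n_random >= 1L, n_random_perm >= 1L, n_perm >= 0L,
            hub_threshold > 0)
  structure(list(cohort = cohort, sweep = sweep,
                 fixed_density = fixed_density,
                 n_random = as.integer(n_random),
                 n_random_perm = as.integer(n_random_perm),
                 n_perm = as.integer(n_perm),
                 hub_threshold = hub_threshold,
                 seed_rois = seed_rois,
                 sweep_metrics = sweep_metrics,
                 seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

.child_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1009 + offset) %% 2147483587)
}

.stage <- function(name, out_dir, warnings_env, expr) {
  message("[metabnet] stage: ", name)
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage '", name, "': ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    }),
    warning = function(w) {
      warnings_env$log <- c(warnings_env$log,
                            paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
}

#' Run the full metabolic network analysis pipeline
#'
#' End-to-end run over a multi-group cohort: simulate or load the cohort;
#' per group, build the covariate-adjusted partial-correlation matrix
#' (written as square CSV) and its global metrics with small-world
#' indices across the density sweep; select the fixed density (lowest
#' full-connection density of the first group, by default); compute
#' nodal betweenness and hub tables at the fixed density; run all
#' pairwise permutation comparisons of the sweep metrics plus nodal `b`
#' at the fixed density; run the seed connectivity comparisons; and
#' write a JSON manifest with every parameter and derived seed so the
#' run can be reproduced exactly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the key in-memory results and the
#'   manifest. All tables are also written as CSV under
#'   `config$out_dir`; a stage failure leaves a `FAILED` marker file
#'   there alongside any partial outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wl <- new.env()
  wl$log <- character(0)

  cohort <- .stage("cohort", config$out_dir, wl, {
    co <- config$cohort
    if (inherits(co, "cohort_config")) co <- simulate_cohort(co)
    else if (is.character(co)) co <- read_cohort_csv(co)
    stopifnot(inherits(co, "roi_cohort"))
    write_cohort_csv(co, file.path(config$out_dir, "cohort.csv"))
    co
  })
  groups <- unique(cohort$group)
  densities <- sweep_densities(config$sweep)

  matrices <- .stage("networks", config$out_dir, wl, {
    ms <- lapply(groups, function(g)
      partial_correlation_matrix(global_normalize(subset_group(cohort, g))))
    names(ms) <- groups
    for (g in groups)
      write_connectivity_csv(ms[[g]],
        file.path(config$out_dir, paste0("connectivity_", g, ".csv")))
    ms
  })

  fixed_density <- .stage("fixed_density", config$out_dir, wl, {
    if (identical(config$fixed_density, "auto")) {
      tryCatch(lowest_full_connection_density(matrices[[1L]], config$sweep),
               error = function(e) {
                 warning("auto fixed-density rule failed (",
                         conditionMessage(e), "); falling back to 0.15")
                 0.15
               })
    } else config$fixed_density
  })

  global_tab <- .stage("global_metrics", config$out_dir, wl, {
    rows <- list()
    for (g in groups) {
      for (d in densities) {
        bg <- binarize_fixed_density(matrices[[g]], d)
        gm <- global_metrics(bg)
        sw <- small_world_indices(bg, n_random = config$n_random,
                                  seed = .child_seed(config$seed, 101L))
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, density = d, n_edges = edge_count(bg),
          Cp = gm$Cp, Lp = gm$Lp, largest_component = gm$largest_component,
          Cp_rand = sw$Cp_rand, Lp_rand = sw$Lp_rand,
          gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(config$out_dir, "global_metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    tab
  })

  nodal_tab <- .stage("nodal_metrics", config$out_dir, wl, {
    rows <- lapply(groups, function(g) {
      bg <- binarize_fixed_density(matrices[[g]], fixed_density)
      nm <- normalized_betweenness(bg, config$hub_threshold)
      cbind(group = g, as.data.frame(nm))
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(config$out_dir, "nodal_metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    tab
  })

  comparisons <- .stage("comparisons", config$out_dir, wl, {
    out <- list()
    if (length(groups) >= 2L && config$n_perm > 0L) {
      pairs <- utils::combn(groups, 2L, simplify = FALSE)
      for (pr in pairs) {
        cA <- subset_group(cohort, pr[1L])
        cB <- subset_group(cohort, pr[2L])
        key <- paste0(pr[1L], "_vs_", pr[2L])
        tab <- sweep_comparison(cA, cB, metrics = config$sweep_metrics,
                                sweep = config$sweep,
                                n_perm = config$n_perm,
                                seed = .child_seed(config$seed, 211L),
                                n_random = config$n_random_perm,
                                hub_threshold = config$hub_threshold)
        bt <- permutation_test(cA, cB, "b", fixed_density,
                               n_perm = config$n_perm,
                               seed = .child_seed(config$seed, 307L),
                               n_random = config$n_random_perm,
                               hub_threshold = config$hub_threshold)
        btab <- bt$table
        names(btab)[names(btab) == "component"] <- "metric"
        btab <- data.frame(metric = btab$metric, density = fixed_density,
                           observed_diff = btab$observed_diff,
                           critical_value = btab$critical_value,
                           p = btab$p, significant = btab$significant)
        full <- rbind(tab, btab)
        utils::write.csv(full,
          file.path(config$out_dir, paste0("comparisons_", key, ".csv")),
          row.names = FALSE, quote = FALSE)
        out[[key]] <- list(
          table = full,
          significant_ranges = lapply(attr(tab, "significant_densities"),
                                      format_density_ranges,
                                      step = config$sweep$step))
      }
    }
    out
  })

  seedmaps <- .stage("seed_connectivity", config$out_dir, wl, {
    out <- list()
    if (length(groups) >= 2L) {
      pairs <- utils::combn(groups, 2L, simplify = FALSE)
      for (sr in config$seed_rois) {
        if (!sr %in% cohort$roi_labels) {
          warning("seed ROI '", sr, "' not in cohort; skipped")
          next
        }
        for (pr in pairs) {
          sc <- seed_group_comparison(subset_group(cohort, pr[1L]),
                                      subset_group(cohort, pr[2L]), sr)
          key <- paste0(sr, "_", pr[1L], "_vs_", pr[2L])
          utils::write.csv(as.data.frame(sc),
            file.path(config$out_dir, paste0("seedmap_", key, ".csv")),
            row.names = FALSE, quote = FALSE)
          out[[key]] <- sc
        }
      }
    }
    out
  })

  manifest <- .stage("manifest", config$out_dir, wl, {
    mf <- list(
      package = "metabnet",
      version = as.character(utils::packageVersion("metabnet")),
      r_version = as.character(getRversion()),
      master_seed = config$seed,
      child_seeds = list(sigma = .child_seed(config$seed, 101L),
                         sweep_permutations = .child_seed(config$seed, 211L),
                         nodal_permutations = .child_seed(config$seed, 307L)),
      parameters = list(
        sweep = unclass(config$sweep),
        fixed_density_rule = config$fixed_density,
        fixed_density_used = fixed_density,
        n_random = config$n_random,
        n_random_perm = config$n_random_perm,
        n_perm = config$n_perm,
        hub_threshold = config$hub_threshold,
        seed_rois = config$seed_rois,
        sweep_metrics = config$sweep_metrics),
      groups = as.list(table(cohort$group)),
      files = list.files(config$out_dir),
      warnings = wl$log)
    jsonlite::write_json(mf, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    mf
  })

  invisible(list(cohort = cohort, matrices = matrices,
                 fixed_density = fixed_density,
                 global_metrics = global_tab, nodal_metrics = nodal_tab,
                 comparisons = comparisons, seedmaps = seedmaps,
                 manifest = manifest))
}
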
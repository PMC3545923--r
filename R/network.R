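#' Globally normalize a cohort
#'
#' Divides every subject's ROI values by that subject's mean over all
#' ROIs, the ROI-level analogue of normalizing regional glucose
#' metabolism to the individual whole-brain mean. Each output row has
#' mean exactly 1.
#'
#' @param cohort A [roi_cohort()].
#' @return A normalized [roi_cohort()].
#' @export
global_normalize <- function(cohort) {
  stopifnot(inherits(cohort, "roi_cohort"))
  m <- rowMeans(cohort$values)
  if (any(m <= 0)) stop("non-positive subject mean; cannot normalize")
  roi_cohort(cohort$values / m, cohort$covariates, cohort$group,
             cohort$roi_labels)
}

#' Covariate-adjusted interregional correlation matrix
#'
#' Computes, for every ROI pair, the partial correlation across subjects
#' controlling for age, sex and education: each ROI column is regressed
#' on an intercept plus the covariates and the Pearson correlation of the
#' residuals is taken. Zero-variance covariates are dropped with a
#' warning (when all covariates are constant the result equals the plain
#' Pearson correlation matrix). Constant ROI columns get coefficient 0
#' against every partner, with a warning. The diagonal is set to 0 by
#' convention.
#'
#' @param cohort A [roi_cohort()]; needs at least `n_covariates + 4`
#'   subjects.
#' @return An object of class `connectivity_matrix` with fields `r`
#'   (symmetric ROI x ROI matrix, zero diagonal), `n_subjects`,
#'   `n_covariates`, `roi_labels`.
#' @export
partial_correlation_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "roi_cohort"))
  X <- cohort$values
  n <- nrow(X)
  covs <- as.matrix(cohort$covariates[, c("age", "sex", "education")])
  keep <- apply(covs, 2L, function(v) stats::var(v) > 0)
  if (!all(keep))
    warning("dropping zero-variance covariate(s): ",
            paste(colnames(covs)[!keep], collapse = ", "))
  Z <- cbind(`(Intercept)` = 1, covs[, keep, drop = FALSE])
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    warning("rank-deficient covariate matrix; dropping degenerate column(s)")
    Z <- Z[, qz$pivot[seq_len(qz$rank)], drop = FALSE]
    qz <- qr(Z)
  }
  n_cov <- ncol(Z) - 1L
  if (n < n_cov + 4L)
    stop("need at least ", n_cov + 4L, " subjects, got ", n)
  res <- qr.resid(qz, X)
  sds <- apply(res, 2L, stats::sd)
  constant <- sds < .Machine$double.eps^0.5
  R <- suppressWarnings(stats::cor(res))
  if (any(constant)) {
    warning("constant ROI column(s) with zero residual variance set to ",
            "coefficient 0: ",
            paste(cohort$roi_labels[constant], collapse = ", "))
    R[constant, ] <- 0
    R[, constant] <- 0
  }
  R <- (R + t(R)) / 2
  R <- pmin(pmax(R, -1), 1)
  diag(R) <- 0
  dimnames(R) <- list(cohort$roi_labels, cohort$roi_labels)
  structure(list(r = R, n_subjects = n, n_covariates = 3L,
                 roi_labels = cohort$roi_labels),
            class = "connectivity_matrix")
}

#' Wrap an existing coefficient matrix as a connectivity matrix
#'
#' @param r Symmetric numeric matrix of correlation coefficients in
#'   `[-1, 1]`; the diagonal is zeroed.
#' @param roi_labels Node labels; defaults to `rownames(r)` or `V1..Vn`.
#' @param n_subjects,n_covariates Provenance counts (optional).
#' @return A `connectivity_matrix`.
#' @export
connectivity_matrix <- function(r, roi_labels = NULL, n_subjects = NA_integer_,
                                n_covariates = NA_integer_) {
  r <- as.matrix(r)
  stopifnot(nrow(r) == ncol(r), isTRUE(all.equal(r, t(r))),
            all(abs(r[upper.tri(r)]) <= 1))
  if (is.null(roi_labels))
    roi_labels <- if (!is.null(rownames(r))) rownames(r) else
      paste0("V", seq_len(nrow(r)))
  diag(r) <- 0
  dimnames(r) <- list(roi_labels, roi_labels)
  structure(list(r = r, n_subjects = n_subjects,
                 n_covariates = n_covariates, roi_labels = roi_labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", length(x$roi_labels), " x ",
      length(x$roi_labels), " (n = ", x$n_subjects, " subjects, ",
      x$n_covariates, " covariates adjusted)\n", sep = "")
  invisible(x)
}

#' Construct a binary undirected graph object
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @param roi_labels Node labels.
#' @return An object of class `binary_graph` with fields `adjacency`,
#'   `density` (realized edge fraction) and `roi_labels`.
#' @export
binary_graph <- function(adjacency, roi_labels = NULL) {
  A <- as.matrix(adjacency)
  stopifnot(nrow(A) == ncol(A), all(A %in% c(0, 1)),
            all(diag(A) == 0), isTRUE(all.equal(A, t(A))))
  if (is.null(roi_labels))
    roi_labels <- if (!is.null(rownames(A))) rownames(A) else
      paste0("V", seq_len(nrow(A)))
  dimnames(A) <- list(roi_labels, roi_labels)
  n <- nrow(A)
  structure(list(adjacency = A,
                 density = sum(A[upper.tri(A)]) / (n * (n - 1) / 2),
                 roi_labels = roi_labels),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat("<binary_graph> ", n, " nodes, ", sum(x$adjacency) / 2,
      " edges (density ", signif(x$density, 3), ")\n", sep = "")
  invisible(x)
}

#' Number of edges of a binary graph
#' @param graph A [binary_graph()].
#' @return Integer edge count.
#' @export
edge_count <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  as.integer(sum(graph$adjacency) / 2)
}

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
}

#' Binarize a connectivity matrix at a fixed density
#'
#' Ranks the `N(N-1)/2` distinct off-diagonal coefficients by signed value
#' (strongest positive first; set `absolute = TRUE` to rank `|r|`) and
#' keeps the top `K = round(density * N(N-1)/2)` as edges (round half away
#' from zero). Ties are broken deterministically by lower ROI index, then
#' lower partner index. Fixing the density guarantees that graphs from
#' different groups have identical edge counts.
#'
#' @param matrix A `connectivity_matrix`.
#' @param density Target edge fraction in (0, 1].
#' @param absolute Rank by absolute coefficient instead of signed value.
#' @return A [binary_graph()] with exactly `K` edges.
#' @export
binarize_fixed_density <- function(matrix, density, absolute = FALSE) {
  stopifnot(inherits(matrix, "connectivity_matrix"),
            density > 0, density <= 1)
  R <- matrix$r
  n <- nrow(R)
  M <- n * (n - 1L) / 2L
  K <- floor(density * M + 0.5)  # round half away from zero
  if (K < 1L) stop("density ", density, " yields no edges (K < 1)")
  ut <- which(upper.tri(R), arr.ind = TRUE)
  v <- R[ut]
  if (absolute) v <- abs(v)
  ord <- order(-v, ut[, 1L], ut[, 2L])
  sel <- ord[seq_len(K)]
  A <- matrix(0, n, n)
  A[ut[sel, , drop = FALSE]] <- 1
  A <- A + t(A)
  dimnames(A) <- dimnames(R)
  binary_graph(A, matrix$roi_labels)
}

#' Binarize a connectivity matrix at a correlation threshold
#'
#' Places an edge wherever the coefficient exceeds `r_min`; the density
#' field is recomputed from the resulting edge count. An empty graph is
#' permitted (with a warning), and edge sets are nested decreasing in
#' `r_min`.
#'
#' @param matrix A `connectivity_matrix`.
#' @param r_min Correlation threshold in (0, 1).
#' @return A [binary_graph()].
#' @export
binarize_r_threshold <- function(matrix, r_min) {
  stopifnot(inherits(matrix, "connectivity_matrix"), r_min > 0, r_min < 1)
  A <- (matrix$r > r_min) * 1
  diag(A) <- 0
  g <- binary_graph(A, matrix$roi_labels)
  if (edge_count(g) == 0L)
    warning("r_min = ", r_min, " leaves an empty graph")
  g
}

#' Density sweep specification
#'
#' The default sweep covers densities 6% to 40% in 1% steps, the range
#' over which small-world estimation on 90-node brain graphs is
#' considered reliable; it contains exactly 35 levels.
#'
#' @param d_min,d_max,step Sweep bounds and increment (fractions).
#' @return Object of class `density_sweep`.
#' @export
density_sweep <- function(d_min = 0.06, d_max = 0.40, step = 0.01) {
  stopifnot(d_min > 0, d_min <= d_max, d_max < 1, step > 0)
  structure(list(d_min = d_min, d_max = d_max, step = step),
            class = "density_sweep")
}

#' Density levels of a sweep
#' @param sweep A [density_sweep()].
#' @return Numeric vector of densities, `floor((d_max-d_min)/step)+1` long.
#' @export
sweep_densities <- function(sweep) {
  stopifnot(inherits(sweep, "density_sweep"))
  len <- floor((sweep$d_max - sweep$d_min) / sweep$step + 1e-9) + 1L
  sweep$d_min + sweep$step * (seq_len(len) - 1L)
}

#' Read / write a connectivity matrix as square CSV
#'
#' @param matrix A `connectivity_matrix`.
#' @param path File path. The CSV has ROI labels as header and row names.
#' @return `read_connectivity_csv()` returns a `connectivity_matrix`.
#' @export
write_connectivity_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  utils::write.csv(matrix$r, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  connectivity_matrix(as.matrix(df), roi_labels = rownames(df))
}

#' Write a binary graph as an edge-list CSV (`roi_a,roi_b`)
#'
#' @param graph A [binary_graph()].
#' @param path File path.
#' @export
write_edgelist_csv <- function(graph, path) {
  stopifnot(inherits(graph, "binary_graph"))
  ut <- which(upper.tri(graph$adjacency) & graph$adjacency == 1,
              arr.ind = TRUE)
  df <- data.frame(roi_a = graph$roi_labels[ut[, 1L]],
                   roi_b = graph$roi_labels[ut[, 2L]])
  df <- df[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build one group's binary network from a cohort
#'
#' Convenience wrapper chaining [global_normalize()],
#' [partial_correlation_matrix()] and [binarize_fixed_density()].
#'
#' @param cohort A [roi_cohort()] (all groups or one).
#' @param density Target density.
#' @param group Optional group label to subset first.
#' @return A [binary_graph()].
#' @export
group_network <- function(cohort, density, group = NULL) {
  if (!is.null(group)) cohort <- subset_group(cohort, group)
  binarize_fixed_density(
    partial_correlation_matrix(global_normalize(cohort)), density)
}
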
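#' ROI time-series container
#'
#' @param subject_id subject identifier.
#' @param data T x R numeric matrix (rows = timepoints, columns = ROIs), no
#'   missing values, every column with nonzero variance.
#' @param roi_labels character vector of R ROI labels.
#' @return a `roi_timeseries` object.
#' @export
roi_timeseries <- function(subject_id, data, roi_labels = colnames(data)) {
  data <- as.matrix(data)
  if (is.null(roi_labels)) roi_labels <- default_roi_labels(ncol(data))
  stopifnot(is.character(subject_id), length(subject_id) == 1,
            length(roi_labels) == ncol(data))
  if (nrow(data) < 2) stopf("time series needs >= 2 timepoints")
  if (anyNA(data) || any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1, ]
    stopf("non-finite value at timepoint %d, ROI '%s' (subject %s)",
          bad[1], roi_labels[bad[2]], subject_id)
  }
  colnames(data) <- roi_labels
  structure(list(subject_id = subject_id, data = data,
                 roi_labels = roi_labels),
            class = "roi_timeseries")
}

#' Correlation-matrix container
#'
#' @param values symmetric R x R matrix with unit diagonal.
#' @param roi_labels ROI labels.
#' @return a `correlation_matrix` object.
#' @export
correlation_matrix <- function(values, roi_labels = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(roi_labels)) roi_labels <- default_roi_labels(ncol(values))
  if (!is_symmetric_matrix(values, tol = 1e-12)) {
    stopf("correlation matrix must be symmetric (tolerance 1e-12)")
  }
  diag(values) <- 1
  dimnames(values) <- list(roi_labels, roi_labels)
  structure(list(values = values, roi_labels = roi_labels),
            class = "correlation_matrix")
}

#' Pearson correlation matrix of one subject's ROI time series
#'
#' @param ts a [roi_timeseries()].
#' @return a [correlation_matrix()] of all pairwise Pearson correlations
#'   between ROI columns.
#' @export
compute_correlation <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  sds <- apply(ts$data, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("zero-variance ROI column(s): %s (subject %s)",
          paste(ts$roi_labels[sds == 0], collapse = ", "), ts$subject_id)
  }
  r <- stats::cor(ts$data)
  r <- (r + t(r)) / 2  # enforce exact symmetry against rounding
  correlation_matrix(r, ts$roi_labels)
}

#' Zero out negative correlations
#'
#' Negative off-diagonal correlations are set to zero and positive ones
#' retained; the unit diagonal is untouched. (Negative edges have poor
#' test-retest reliability in binary-graph analyses, so the pipeline builds
#' graphs from positive correlations only.)
#'
#' @param corr a [correlation_matrix()].
#' @param mode `"zero"` (default) or `"absolute"` (takes `|r|` instead, the
#'   usual robustness variant).
#' @return a [correlation_matrix()].
#' @export
zero_negatives <- function(corr, mode = c("zero", "absolute")) {
  stopifnot(inherits(corr, "correlation_matrix"))
  mode <- match.arg(mode)
  v <- corr$values
  v <- if (mode == "zero") pmax(v, 0) else abs(v)
  diag(v) <- 1
  correlation_matrix(v, corr$roi_labels)
}

#' Fisher r-to-z transform of a correlation matrix
#'
#' Applies `atanh` off-diagonal; the diagonal is set to 0.
#'
#' @param corr a [correlation_matrix()].
#' @return matrix of z-scores with zero diagonal.
#' @export
fisher_z <- function(corr) {
  stopifnot(inherits(corr, "correlation_matrix"))
  v <- corr$values
  off <- row(v) != col(v)
  if (any(abs(v[off]) >= 1)) {
    stopf("off-diagonal |r| = 1: Fisher z is undefined")
  }
  z <- v
  z[off] <- atanh(v[off])
  diag(z) <- 0
  z
}

# number of edges implied by sparsity S on R nodes (round half away from zero)
target_edges <- function(S, n_nodes) {
  round_half_up(S * n_nodes * (n_nodes - 1) / 2)
}

#' Binarize a nonnegative correlation matrix at a sparsity level
#'
#' Sparsity `S` is the ratio of retained edges to the `R(R-1)/2` possible
#' pairs. The `round(S * R(R-1)/2)` strongest strictly positive pairs become
#' edges, applying a subject-specific correlation cutoff so all subjects end
#' up with the same edge count. Ties are broken by (row, column) order after
#' sorting by value, for determinism. If fewer strictly positive pairs exist
#' than requested, the edge count is clamped with a warning.
#'
#' @param corr a [correlation_matrix()] with nonnegative off-diagonal.
#' @param S sparsity in (0, 1).
#' @return symmetric logical adjacency matrix with zero diagonal and
#'   attribute `n_edges`.
#' @export
binarize_at_sparsity <- function(corr, S) {
  stopifnot(inherits(corr, "correlation_matrix"))
  assert_scalar_number(S, "S")
  if (S <= 0 || S >= 1) stopf("sparsity S must lie in (0, 1)")
  v <- corr$values
  r <- nrow(v)
  ut <- which(upper.tri(v))
  if (any(v[ut] < 0)) stopf("binarization expects nonnegative off-diagonal values")
  want <- target_edges(S, r)
  pos <- ut[v[ut] > 0]
  if (length(pos) < want) {
    warnf("sparsity %.3f requests %d edges but only %d positive pairs exist; clamping",
          S, want, length(pos))
    want <- length(pos)
  }
  adj <- matrix(FALSE, r, r, dimnames = list(corr$roi_labels, corr$roi_labels))
  if (want > 0) {
    ord <- pos[order(-v[pos], pos)]  # value desc, then (i,j) lexicographic
    keep <- ord[seq_len(want)]
    adj[keep] <- TRUE
    adj <- adj | t(adj)
  }
  attr(adj, "n_edges") <- want
  adj
}

# inclusive arithmetic sparsity grid with 1e-9 endpoint tolerance
sparsity_grid <- function(s_min, s_max, step) {
  assert_scalar_number(s_min, "s_min")
  assert_scalar_number(s_max, "s_max")
  assert_scalar_number(step, "step")
  if (s_min >= s_max) stopf("s_min must be < s_max")
  if (step <= 0) stopf("step must be > 0")
  k <- floor((s_max - s_min) / step + 1e-9)
  grid <- s_min + step * (0:k)
  grid[abs(grid - s_max) < 1e-9] <- s_max
  grid
}

#' Sweep sparsity thresholds to build a binary graph stack
#'
#' Builds one binarized graph per sparsity level on the inclusive grid
#' `s_min, s_min + step, ..., s_max`. Thresholds are applied independently
#' per level; edge counts grow with S but slices need not be nested.
#'
#' @param corr a [correlation_matrix()] with nonnegative off-diagonal (see
#'   [zero_negatives()]).
#' @param s_min,s_max sparsity range, `0 < s_min < s_max < 1`. Defaults span
#'   the conventional 0.10-0.30 range.
#' @param step grid step (default 0.01).
#' @return a `binary_graph_stack`: list with `adjacency` (R x R x n_S
#'   logical array), `sparsity_grid`, `roi_labels`, `n_edges`.
#' @export
threshold_sweep <- function(corr, s_min = 0.10, s_max = 0.30, step = 0.01) {
  stopifnot(inherits(corr, "correlation_matrix"))
  grid <- sparsity_grid(s_min, s_max, step)
  if (length(grid) < 2) {
    stopf("sparsity grid has %d point(s); need >= 2 for AUC integration",
          length(grid))
  }
  r <- nrow(corr$values)
  adj <- array(FALSE, dim = c(r, r, length(grid)),
               dimnames = list(corr$roi_labels, corr$roi_labels, NULL))
  n_edges <- integer(length(grid))
  for (k in seq_along(grid)) {
    a <- binarize_at_sparsity(corr, grid[k])
    n_edges[k] <- attr(a, "n_edges")
    adj[, , k] <- a
  }
  structure(list(adjacency = adj, sparsity_grid = grid,
                 roi_labels = corr$roi_labels, n_edges = n_edges),
            class = "binary_graph_stack")
}
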
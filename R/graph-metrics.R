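#' Nodal degree of a binary graph
#'
#' @param adj symmetric logical/0-1 adjacency matrix with zero diagonal.
#' @return integer vector of row sums (number of direct neighbours).
#' @export
nodal_degree <- function(adj) {
  adj <- check_adjacency(adj)
  rowSums(adj)
}

#' Unweighted shortest-path lengths
#'
#' All-pairs breadth-first-search distances, run level-synchronously for
#' all sources at once via boolean matrix products (the reachability
#' frontier is expanded one hop per iteration, so the loop runs diameter
#' times). Unreachable pairs are `Inf`, the diagonal 0.
#'
#' @param adj symmetric logical adjacency matrix with zero diagonal.
#' @return R x R numeric distance matrix.
#' @export
shortest_paths_matrix <- function(adj) {
  adj <- check_adjacency(adj)
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  d[adj] <- 1
  a_num <- adj * 1
  reach <- adj
  diag(reach) <- TRUE
  len <- 1
  repeat {
    reach2 <- (reach %*% a_num > 0) | reach
    new <- reach2 & !reach
    if (!any(new)) break
    len <- len + 1
    d[new] <- len
    reach <- reach2
  }
  d
}

#' Nodal global efficiency
#'
#' For node i, the mean over the other N-1 nodes of the inverse shortest
#' path length (inverse harmonic mean of distances); unreachable targets
#' contribute 0, so the metric is defined on disconnected graphs and lies
#' in \[0, 1\].
#'
#' @param adj symmetric logical adjacency matrix with zero diagonal, R >= 2.
#' @return numeric vector of per-node efficiencies.
#' @export
nodal_global_efficiency <- function(adj) {
  adj <- check_adjacency(adj)
  n <- nrow(adj)
  if (n < 2) stopf("global efficiency needs >= 2 nodes")
  d <- shortest_paths_matrix(adj)
  inv <- 1 / d
  diag(inv) <- 0          # exclude j = i
  inv[is.infinite(d)] <- 0  # unreachable targets contribute 0
  rowSums(inv) / (n - 1)
}

#' Trapezoidal AUC of per-threshold nodal values
#'
#' Integrates each node's metric profile over the sparsity grid with the
#' composite trapezoid rule, condensing a threshold sweep into one number
#' per node.
#'
#' @param values R x n_S matrix (nodes x thresholds).
#' @param grid strictly increasing sparsity grid of length n_S >= 2.
#' @return numeric vector of length R.
#' @export
metric_auc <- function(values, grid) {
  values <- as.matrix(values)
  if (length(grid) < 2) stopf("AUC needs a grid of >= 2 points")
  if (any(diff(grid) <= 0)) stopf("sparsity grid must be strictly increasing")
  if (ncol(values) != length(grid)) {
    stopf("values have %d columns but grid has %d points",
          ncol(values), length(grid))
  }
  h <- diff(grid)
  w <- c(h / 2, 0) + c(0, h / 2)  # trapezoid weights
  as.vector(values %*% w)
}

#' Nodal AUC metrics of one subject's graph stack
#'
#' Computes degree and global efficiency for every slice of the stack and
#' integrates each as AUC over the sparsity grid.
#'
#' @param stack a [threshold_sweep()] result.
#' @param subject_id subject identifier carried into the result.
#' @param keep_per_threshold keep the per-threshold metric matrices?
#' @return a `nodal_metrics_auc` object: list with `subject_id`,
#'   `degree_auc`, `efficiency_auc` (named R-vectors), `sparsity_grid`, and
#'   (optionally) `degree` and `efficiency` R x n_S matrices.
#' @export
subject_metrics <- function(stack, subject_id = "subject",
                            keep_per_threshold = FALSE) {
  stopifnot(inherits(stack, "binary_graph_stack"))
  grid <- stack$sparsity_grid
  r <- length(stack$roi_labels)
  deg <- matrix(NA_real_, r, length(grid),
                dimnames = list(stack$roi_labels, NULL))
  eff <- deg
  for (k in seq_along(grid)) {
    a <- stack$adjacency[, , k]
    deg[, k] <- nodal_degree(a)
    eff[, k] <- nodal_global_efficiency(a)
  }
  out <- list(subject_id = subject_id,
              degree_auc = metric_auc(deg, grid),
              efficiency_auc = metric_auc(eff, grid),
              sparsity_grid = grid)
  names(out$degree_auc) <- names(out$efficiency_auc) <- stack$roi_labels
  if (keep_per_threshold) {
    out$degree <- deg
    out$efficiency <- eff
  }
  structure(out, class = "nodal_metrics_auc")
}

#' Nodal AUC metrics for a whole cohort
#'
#' Runs negative zeroing, the sparsity sweep and AUC integration for every
#' subject and stacks the results into subjects x nodes matrices.
#'
#' @param timeseries list of [roi_timeseries()] objects.
#' @param s_min,s_max,step sparsity sweep settings (see [threshold_sweep()]).
#' @param negative_handling passed to [zero_negatives()].
#' @return list with matrices `degree_auc` and `efficiency_auc`
#'   (rownames = subject ids, colnames = ROI labels) and `sparsity_grid`.
#' @export
cohort_metrics <- function(timeseries, s_min = 0.10, s_max = 0.30,
                           step = 0.01, negative_handling = "zero") {
  stopifnot(length(timeseries) > 0)
  labels <- timeseries[[1]]$roi_labels
  ids <- vapply(timeseries, function(t) t$subject_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate subject ids in time-series list")
  deg <- matrix(NA_real_, length(ids), length(labels),
                dimnames = list(ids, labels))
  eff <- deg
  grid <- NULL
  for (s in seq_along(timeseries)) {
    corr <- zero_negatives(compute_correlation(timeseries[[s]]),
                           mode = negative_handling)
    stack <- threshold_sweep(corr, s_min, s_max, step)
    m <- subject_metrics(stack, subject_id = ids[s])
    deg[s, ] <- m$degree_auc
    eff[s, ] <- m$efficiency_auc
    grid <- m$sparsity_grid
  }
  list(degree_auc = deg, efficiency_auc = eff, sparsity_grid = grid)
}

check_adjacency <- function(adj) {
  adj <- as.matrix(adj)
  storage.mode(adj) <- "logical"
  if (nrow(adj) != ncol(adj)) stopf("adjacency must be square")
  if (any(diag(adj))) stopf("adjacency must have a zero diagonal")
  if (!identical(adj, t(adj))) stopf("adjacency must be symmetric")
  adj
}
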
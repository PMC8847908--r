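# Covariate-adjusted association of nodal metrics / connectivity with the
# analytic-holistic style score.

#' Partial correlation of two variables given covariates
#'
#' Correlates the least-squares residuals of `x` and `y` after removing the
#' covariates (with intercept). The p-value uses a t reference with
#' `n - 2 - k` degrees of freedom, `k` = number of covariate columns.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data frame of covariate columns, or
#'   `NULL` for a plain Pearson correlation.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stopf("x and y lengths differ")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("non-finite inputs")
  if (is.null(covariates)) {
    cv <- matrix(numeric(0), n, 0)
  } else {
    cv <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  }
  k <- ncol(cv)
  if (n <= k + 2) stopf("need n > k + 2 observations (n = %d, k = %d)", n, k)
  q <- qr(cbind(1, cv))
  rx <- qr.resid(q, x)
  ry <- qr.resid(q, y)
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1)) {
    stopf("constant residuals after covariate removal; partial correlation undefined")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df, n = n)
}

#' Screen nodal metrics for association with the style score
#'
#' Partially correlates each (node, metric) pair with the AHS-like score,
#' controlling the covariates, and controls FDR across all tested metrics
#' jointly. Subjects with a missing score are dropped (count reported via
#' message).
#'
#' @param metrics list with `degree_auc` and `efficiency_auc` matrices
#'   (subjects x nodes, rownames = subject ids).
#' @param phenotypes phenotype table with `subject_id`, `ahs` and covariate
#'   columns.
#' @param nodes ROI labels to test (e.g. the consistent nodes from
#'   [screen_nodes()]); defaults to all nodes.
#' @param q_level FDR level.
#' @param covariates covariate column names (default sex, age, motion).
#' @return list with `table` (item, node, metric, r, p, q, n), `selected`
#'   (significant rows, with `sign`) and `n_dropped`.
#' @export
metric_ahs_screen <- function(metrics, phenotypes, nodes = NULL,
                              q_level = 0.05,
                              covariates = c("age", "sex", "motion")) {
  if (is.null(nodes)) nodes <- colnames(metrics$degree_auc)
  missing_nodes <- setdiff(nodes, colnames(metrics$degree_auc))
  if (length(missing_nodes)) {
    stopf("unknown node(s): %s", paste(missing_nodes, collapse = ", "))
  }
  keep <- !is.na(phenotypes$ahs)
  n_dropped <- sum(!keep)
  if (n_dropped) message(n_dropped, " subject(s) without a style score dropped")
  ph <- phenotypes[keep, , drop = FALSE]
  idx <- match(ph$subject_id, rownames(metrics$degree_auc))
  if (anyNA(idx)) stopf("metrics missing for scored subject(s)")
  cv <- ph[, covariates, drop = FALSE]

  grid <- expand.grid(node = nodes, metric = c("degree", "efficiency"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mat <- if (grid$metric[i] == "degree") metrics$degree_auc else metrics$efficiency_auc
    pc <- partial_correlation(mat[idx, grid$node[i]], ph$ahs, cv)
    data.frame(item = paste(grid$metric[i], grid$node[i], sep = ":"),
               node = grid$node[i], metric = grid$metric[i],
               r = pc$r, p = pc$p, n = pc$n, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  bh <- fdr_bh(tab$p, q_level)
  tab$q <- bh$adjusted
  sel <- tab[bh$rejected, , drop = FALSE]
  sel$sign <- ifelse(sel$r >= 0, 1L, -1L)
  list(table = tab, selected = sel, n_dropped = n_dropped, q_level = q_level)
}

#' Per-subject functional connectivity of one node with all others
#'
#' @param seed_node ROI label.
#' @param timeseries list of [roi_timeseries()].
#' @param use_fisher_z apply the Fisher r-to-z transform to the
#'   correlations?
#' @return subjects x (R-1) matrix of connectivity values (rownames =
#'   subject ids, colnames = partner ROI labels).
#' @export
node_fc <- function(seed_node, timeseries, use_fisher_z = FALSE) {
  labels <- timeseries[[1]]$roi_labels
  if (!seed_node %in% labels) stopf("unknown seed node '%s'", seed_node)
  partners <- setdiff(labels, seed_node)
  ids <- vapply(timeseries, function(t) t$subject_id, character(1))
  fc <- matrix(NA_real_, length(ids), length(partners),
               dimnames = list(ids, partners))
  for (s in seq_along(timeseries)) {
    x <- timeseries[[s]]$data
    r <- stats::cor(x[, seed_node], x[, partners])
    if (use_fisher_z) r <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    fc[s, ] <- r
  }
  fc
}

#' Screen one node's connectivity for association with the style score
#'
#' For a seed node, computes each subject's functional connectivity (time-
#' series Pearson correlation, optionally Fisher-z) to each of the other
#' R-1 nodes, partially correlates it with the AHS-like score, and controls
#' FDR across the R-1 tests (one family per seed node).
#'
#' @inheritParams metric_ahs_screen
#' @inheritParams node_fc
#' @return list with `table` (partner, r, p, q, n) and `selected`.
#' @export
node_fc_ahs_screen <- function(seed_node, timeseries, phenotypes,
                               q_level = 0.05,
                               covariates = c("age", "sex", "motion"),
                               use_fisher_z = FALSE) {
  fc <- node_fc(seed_node, timeseries, use_fisher_z)
  keep <- !is.na(phenotypes$ahs)
  ph <- phenotypes[keep, , drop = FALSE]
  idx <- match(ph$subject_id, rownames(fc))
  if (anyNA(idx)) stopf("time series missing for scored subject(s)")
  cv <- ph[, covariates, drop = FALSE]
  rows <- lapply(colnames(fc), function(partner) {
    pc <- partial_correlation(fc[idx, partner], ph$ahs, cv)
    data.frame(seed = seed_node, partner = partner, r = pc$r, p = pc$p,
               n = pc$n, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  bh <- fdr_bh(tab$p, q_level)
  tab$q <- bh$adjusted
  list(table = tab, selected = tab[bh$rejected, , drop = FALSE],
       q_level = q_level)
}
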
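# Composite predictors, cross-validated prediction/classification,
# permutation calibration, and the CPM-style variant with within-fold
# feature selection.

#' Sign-unify metric columns
#'
#' Multiplies each metric column by its association sign so that, after
#' unification, every member correlates nonnegatively with the outcome on
#' the sample used to fix the signs.
#'
#' @param metric_matrix subjects x metrics matrix.
#' @param signs vector of +1/-1, one per column.
#' @return matrix with flipped columns.
#' @export
unify_directions <- function(metric_matrix, signs) {
  metric_matrix <- as.matrix(metric_matrix)
  if (length(signs) != ncol(metric_matrix)) stopf("one sign per column required")
  if (any(!signs %in% c(-1, 1))) stopf("signs must be +1 or -1 (zero not allowed)")
  sweep(metric_matrix, 2, signs, `*`)
}

#' Build composite predictors from selected metrics
#'
#' Averages the sign-unified degree members into `t_deg` and the
#' sign-unified efficiency members into `t_eg`, one value per subject.
#' A family with no members yields a `NULL` composite.
#'
#' @param metrics list with `degree_auc` and `efficiency_auc` matrices
#'   (subjects x nodes).
#' @param selection data frame with columns `node`, `metric`
#'   (`"degree"`/`"efficiency"`) and `sign` (+1/-1).
#' @return a `composite_predictors` list: `t_deg`, `t_eg`, `members`.
#' @export
build_composites <- function(metrics, selection) {
  stopifnot(is.data.frame(selection),
            all(c("node", "metric", "sign") %in% names(selection)))
  comp <- function(metric_name) {
    sel <- selection[selection$metric == metric_name, , drop = FALSE]
    if (!nrow(sel)) return(NULL)
    mat <- if (metric_name == "degree") metrics$degree_auc else metrics$efficiency_auc
    missing_nodes <- setdiff(sel$node, colnames(mat))
    if (length(missing_nodes)) {
      stopf("selected %s metric(s) missing: %s", metric_name,
            paste(missing_nodes, collapse = ", "))
    }
    rowMeans(unify_directions(mat[, sel$node, drop = FALSE], sel$sign))
  }
  structure(list(t_deg = comp("degree"), t_eg = comp("efficiency"),
                 members = selection),
            class = "composite_predictors")
}

composite_design <- function(composites) {
  x <- cbind(t_deg = composites$t_deg, t_eg = composites$t_eg)
  if (is.null(x) || ncol(x) == 0) stopf("no composite predictors available")
  x
}

# fold assignment; stratified by `strata` when given
make_folds <- function(n, k, strata = NULL) {
  if (is.null(strata)) {
    return(sample(rep(seq_len(k), length.out = n)))
  }
  folds <- integer(n)
  for (lev in unique(strata)) {
    idx <- which(strata == lev)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

#' K-fold cross-validated linear prediction of a continuous outcome
#'
#' Randomly partitions subjects into `k` folds, fits ordinary least squares
#' on each training set and predicts the held-out fold, so every subject is
#' predicted exactly once. Predictive power is the Pearson correlation
#' between out-of-fold predictions and observations.
#'
#' @param x subjects x predictors matrix (e.g. the two composites).
#' @param y continuous outcome, no missing values.
#' @param k number of folds (default 10).
#' @param seed integer seed, or `NULL` to draw folds from the current RNG
#'   stream.
#' @return a `prediction_outcome` list: `observed`, `predicted`,
#'   `estimate` (r), `folds`, `k`.
#' @export
kfold_predict_continuous <- function(x, y, k = 10, seed = NULL) {
  x <- as.matrix(x)
  n <- length(y)
  if (nrow(x) != n) stopf("x rows != length(y)")
  if (anyNA(y) || anyNA(x)) stopf("missing values in predictors or outcome")
  if (n < 2 * k) stopf("need n >= 2k subjects (n = %d, k = %d)", n, k)
  with_seed(seed, {
    folds <- make_folds(n, k)
    predicted <- numeric(n)
    for (f in seq_len(k)) {
      test <- folds == f
      if (sum(!test) < ncol(x) + 2) {
        stopf("fold %d leaves %d training rows for %d predictors", f,
              sum(!test), ncol(x))
      }
      fit <- stats::lm.fit(cbind(1, x[!test, , drop = FALSE]), y[!test])
      predicted[test] <- cbind(1, x[test, , drop = FALSE]) %*% fit$coefficients
    }
    structure(list(observed = y, predicted = predicted,
                   estimate = stats::cor(predicted, y), folds = folds,
                   k = k, type = "continuous"),
              class = "prediction_outcome")
  })
}

#' K-fold cross-validated logistic classification
#'
#' Stratified fold assignment (both classes in every fold), fold-wise
#' logistic regression, out-of-fold class assignment by thresholding the
#' predicted probability at `cutoff` (predictions above the cutoff are
#' assigned class 1). The estimate is overall accuracy; per-group
#' accuracies are reported for class 0 and class 1.
#'
#' @param x subjects x predictors matrix.
#' @param labels 0/1 class labels.
#' @param k folds (default 10).
#' @param seed integer seed or `NULL`.
#' @param cutoff probability cutoff (default 0.5).
#' @return a `prediction_outcome` list with `estimate` (accuracy) and
#'   `per_group_accuracy`.
#' @export
kfold_classify <- function(x, labels, k = 10, seed = NULL, cutoff = 0.5) {
  x <- as.matrix(x)
  n <- length(labels)
  if (nrow(x) != n) stopf("x rows != length(labels)")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    stopf("labels must be 0/1 with both classes present")
  }
  with_seed(seed, {
    for (attempt in 1:25) {
      folds <- make_folds(n, k, strata = labels)
      ok <- all(vapply(seq_len(k), function(f) {
        length(unique(labels[folds != f])) == 2
      }, logical(1)))
      if (ok) break
      warnf("single-class training fold; redrawing stratified folds")
    }
    prob <- numeric(n)
    for (f in seq_len(k)) {
      test <- folds == f
      df <- data.frame(y = labels[!test], x[!test, , drop = FALSE])
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      nd <- data.frame(x[test, , drop = FALSE])
      prob[test] <- suppressWarnings(stats::predict(fit, newdata = nd,
                                                    type = "response"))
    }
    predicted <- as.integer(prob > cutoff)
    structure(list(observed = labels, predicted = predicted,
                   probability = prob,
                   estimate = mean(predicted == labels),
                   per_group_accuracy = c(
                     `0` = mean(predicted[labels == 0] == 0),
                     `1` = mean(predicted[labels == 1] == 1)),
                   folds = folds, k = k, cutoff = cutoff,
                   type = "classification"),
              class = "prediction_outcome")
  })
}

#' Permutation calibration of a cross-validated estimate
#'
#' Reshuffles the outcome across subjects `n_perm` times, reruns the full
#' cross-validation each time, and summarises the null distribution by the
#' values at sorted positions `floor(0.025 n_perm)` and
#' `floor(0.975 n_perm)` (positions 25 and 975 for 1000 permutations). The
#' observed estimate is significant when it exceeds the upper bound; a
#' permutation p-value `(1 + #\{null >= observed\}) / (n_perm + 1)` is
#' reported alongside.
#'
#' @param procedure function taking a permuted outcome vector and returning
#'   a scalar estimate (it should consume the current RNG stream for its
#'   own fold draws).
#' @param outcome the outcome vector to permute.
#' @param observed the observed estimate being calibrated.
#' @param n_perm number of permutations (>= 40 so the positions exist).
#' @param seed integer seed or `NULL`.
#' @return list with `null_distribution`, `ci95`, `significant`, `p_perm`.
#' @export
permutation_calibrate <- function(procedure, outcome, observed,
                                  n_perm = 1000, seed = NULL) {
  if (n_perm < 40) stopf("n_perm must be >= 40 (got %d)", n_perm)
  with_seed(seed, {
    null_dist <- vapply(seq_len(n_perm), function(b) {
      procedure(outcome[sample.int(length(outcome))])
    }, numeric(1))
    srt <- sort(null_dist)
    ci95 <- c(lower = srt[floor(0.025 * n_perm)],
              upper = srt[floor(0.975 * n_perm)])
    list(null_distribution = null_dist, ci95 = ci95,
         significant = observed > ci95[["upper"]],
         p_perm = (1 + sum(null_dist >= observed)) / (n_perm + 1))
  })
}

# correlation + two-sided t-test p for each column of x against y
cor_with_p <- function(x, y) {
  n <- length(y)
  r <- as.vector(stats::cor(x, y))
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), n - 2))
}

#' Connectome-based predictive modeling of a continuous outcome
#'
#' Within each training fold: correlate every nodal metric (all degree and
#' efficiency AUCs) with the outcome, keep metrics with `p < alpha`,
#' sign-unify them on the training data, average them into fold-specific
#' composites, fit OLS and predict the held-out fold. A fold with no
#' selected metric in either family predicts the training mean (with a
#' warning). The estimate is the correlation between out-of-fold
#' predictions and observations.
#'
#' @param metrics list with `degree_auc` and `efficiency_auc` matrices,
#'   rows aligned with `y`.
#' @param y continuous outcome.
#' @param k folds (default 10).
#' @param alpha within-fold selection threshold (default 0.05).
#' @param seed integer seed or `NULL`.
#' @return a `prediction_outcome` with `fold_selections`: one character
#'   vector of `"metric:node"` items per fold.
#' @export
cpm_predict <- function(metrics, y, k = 10, alpha = 0.05, seed = NULL) {
  deg <- as.matrix(metrics$degree_auc)
  eff <- as.matrix(metrics$efficiency_auc)
  n <- length(y)
  stopifnot(nrow(deg) == n, nrow(eff) == n)
  if (n < 2 * k) stopf("need n >= 2k subjects")
  with_seed(seed, {
    folds <- make_folds(n, k)
    predicted <- numeric(n)
    fold_selections <- vector("list", k)
    for (f in seq_len(k)) {
      test <- folds == f
      sel_parts <- list()
      xtr <- NULL
      xte <- NULL
      for (fam in c("degree", "efficiency")) {
        mat <- if (fam == "degree") deg else eff
        ct <- cor_with_p(mat[!test, , drop = FALSE], y[!test])
        keep <- which(ct$p < alpha)
        sel_parts[[fam]] <- if (length(keep)) {
          paste(fam, colnames(mat)[keep], sep = ":")
        } else character(0)
        if (length(keep)) {
          sgn <- ifelse(ct$r[keep] >= 0, 1, -1)
          xtr <- cbind(xtr, rowMeans(unify_directions(
            mat[!test, keep, drop = FALSE], sgn)))
          xte <- cbind(xte, rowMeans(unify_directions(
            mat[test, keep, drop = FALSE], sgn)))
        }
      }
      fold_selections[[f]] <- c(sel_parts$degree, sel_parts$efficiency)
      if (is.null(xtr)) {
        warnf("fold %d selected no metrics at alpha = %g; predicting training mean",
              f, alpha)
        predicted[test] <- mean(y[!test])
      } else {
        fit <- stats::lm.fit(cbind(1, xtr), y[!test])
        predicted[test] <- cbind(1, xte) %*% fit$coefficients
      }
    }
    structure(list(observed = y, predicted = predicted,
                   estimate = stats::cor(predicted, y), folds = folds,
                   k = k, alpha = alpha, fold_selections = fold_selections,
                   type = "continuous"),
              class = "prediction_outcome")
  })
}

#' Stability selection across CV folds
#'
#' Keeps the metrics selected in at least `min_count` of the fold-level
#' selection sets (all 10 folds by default).
#'
#' @param fold_selections list of character vectors of `"metric:node"`
#'   items, as produced by [cpm_predict()].
#' @param min_count minimum number of folds a metric must appear in.
#' @return data frame with `item`, `metric`, `node`, `count`.
#' @export
stability_select <- function(fold_selections, min_count = 10) {
  counts <- table(unlist(fold_selections))
  keep <- names(counts)[counts >= min_count]
  if (!length(keep)) {
    return(data.frame(item = character(0), metric = character(0),
                      node = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keep, ":", fixed = TRUE)
  data.frame(item = keep,
             metric = vapply(parts, `[`, character(1), 1),
             node = vapply(parts, `[`, character(1), 2),
             count = as.integer(counts[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-sample classification from metrics selected on the scored cohort
#'
#' Builds the two composites on the combined two-group sample, using the
#' member metrics and signs fixed on the scored (AHS) cohort, then runs
#' stratified k-fold logistic classification of group membership.
#'
#' @param selection data frame with `node`, `metric`, `sign` (signs from
#'   the scored cohort).
#' @param metrics list with `degree_auc`/`efficiency_auc` for the combined
#'   sample, rows aligned with `labels`.
#' @param labels 0/1 group labels (0 = Western-like, 1 = Eastern-like).
#' @inheritParams kfold_classify
#' @return a `prediction_outcome` (see [kfold_classify()]).
#' @export
cross_sample_classify <- function(selection, metrics, labels, k = 10,
                                  seed = NULL, cutoff = 0.5) {
  comp <- build_composites(metrics, selection)
  kfold_classify(composite_design(comp), labels, k = k, seed = seed,
                 cutoff = cutoff)
}
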
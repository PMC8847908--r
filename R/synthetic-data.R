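#' Construct a ground-truth population network
#'
#' Draws a random symmetric, zero-diagonal, nonnegative edge-weight matrix
#' that plays the role of the (unobserved) population connectome behind a
#' two-group study. Group 1 differs from group 0 at designated effect nodes:
#' every edge incident to at least one effect node has its weight multiplied
#' by `1 + effect_delta` in group 1. The weight matrix implies a sampling
#' covariance via a ridge term (see [implied_covariance()]), so a planted
#' group difference propagates into the time series, the correlation graphs
#' and the nodal metrics rather than being injected into the metrics
#' directly.
#'
#' @param n_nodes number of ROIs (nodes).
#' @param density target fraction of nonzero off-diagonal pairs, in (0, 1).
#' @param effect_nodes integer vector of node indices (1-based) carrying the
#'   group effect; may be empty.
#' @param effect_delta signed scalar; relative weight change at effect-node
#'   edges in group 1. `0` makes the two groups identical.
#' @param seed integer seed; the network is deterministic given the seed.
#' @param weight_range range from which nonzero edge weights are drawn
#'   uniformly.
#' @return an object of class `ground_truth_network`: a list with
#'   `n_nodes`, `base_weights`, `effect_nodes`, `effect_delta`, `lambda`
#'   (the shared positive-definiteness ridge) and `roi_labels`.
#' @export
make_ground_truth <- function(n_nodes, density, effect_nodes = integer(0),
                              effect_delta = 0, seed = NULL,
                              weight_range = c(0.2, 0.6)) {
  assert_scalar_number(n_nodes, "n_nodes", lower = 2)
  assert_scalar_number(density, "density")
  if (density <= 0 || density >= 1) stopf("`density` must lie in (0, 1)")
  effect_nodes <- as.integer(effect_nodes)
  if (length(effect_nodes) &&
      (any(effect_nodes < 1L) || any(effect_nodes > n_nodes) ||
       anyDuplicated(effect_nodes))) {
    stopf("`effect_nodes` must be distinct indices in 1..%d", n_nodes)
  }
  assert_scalar_number(effect_delta, "effect_delta")

  w <- with_seed(seed, {
    n_pairs <- n_nodes * (n_nodes - 1L) / 2L
    k <- max(1L, round_half_up(density * n_pairs))
    chosen <- sample.int(n_pairs, k)
    vals <- stats::runif(k, weight_range[1], weight_range[2])
    m <- matrix(0, n_nodes, n_nodes)
    ut <- which(upper.tri(m))
    m[ut[chosen]] <- vals
    m + t(m)
  })

  net <- structure(
    list(n_nodes = as.integer(n_nodes), base_weights = w,
         effect_nodes = effect_nodes, effect_delta = effect_delta,
         lambda = 0, roi_labels = default_roi_labels(n_nodes)),
    class = "ground_truth_network")

  # Shared ridge: smallest value rendering BOTH group weight matrices
  # positive definite, plus a 0.01 margin, so the groups share a diagonal.
  ev <- vapply(0:1, function(g) {
    min(eigen(group_weights(net, g), symmetric = TRUE,
              only.values = TRUE)$values)
  }, numeric(1))
  net$lambda <- max(0, -min(ev)) + 0.01

  # sanity: implied covariances must be sampleable
  for (g in 0:1) implied_covariance(net, group = g)
  net
}

#' Group-specific edge weights of a ground-truth network
#'
#' @param network a `ground_truth_network`.
#' @param group 0 or 1.
#' @return symmetric weight matrix for the requested group.
#' @export
group_weights <- function(network, group) {
  stopifnot(inherits(network, "ground_truth_network"), group %in% c(0, 1))
  w <- network$base_weights
  if (group == 1 && length(network$effect_nodes)) {
    hit <- matrix(FALSE, nrow(w), ncol(w))
    hit[network$effect_nodes, ] <- TRUE
    hit[, network$effect_nodes] <- TRUE
    diag(hit) <- FALSE
    w[hit] <- w[hit] * (1 + network$effect_delta)
  }
  w
}

#' Implied sampling covariance of a group (or subject) weight matrix
#'
#' The covariance is `W + (lambda + noise_sd^2) * I`, where `lambda` is the
#' network's shared ridge (enlarged if a subject-specific weight matrix
#' needs more to stay positive definite, with the same 0.01 margin).
#'
#' @param network a `ground_truth_network`.
#' @param group 0 or 1.
#' @param noise_sd observation noise standard deviation; adds `noise_sd^2`
#'   to the diagonal.
#' @param subject_gains optional positive per-node gain vector; edge (i, j)
#'   is scaled by `sqrt(gains[i] * gains[j])`, giving a subject-specific
#'   generating network.
#' @return positive-definite covariance matrix.
#' @export
implied_covariance <- function(network, group = 0, noise_sd = 0,
                               subject_gains = NULL) {
  w <- group_weights(network, group)
  if (!is.null(subject_gains)) {
    if (length(subject_gains) != network$n_nodes || any(subject_gains <= 0)) {
      stopf("`subject_gains` must be %d positive values", network$n_nodes)
    }
    s <- sqrt(subject_gains)
    w <- w * outer(s, s)
  }
  ridge <- network$lambda
  emin <- min(eigen(w, symmetric = TRUE, only.values = TRUE)$values)
  if (emin + ridge <= 0.005) ridge <- -emin + 0.01
  sigma <- w + diag(ridge + noise_sd^2, nrow(w))
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stopf(paste0("implied covariance is not positive definite ",
                 "(min eigenvalue of weights %.4g, ridge %.4g); ",
                 "increase noise_sd or reduce weights"), emin, ridge)
  }
  sigma
}

#' Sample one subject's ROI time series
#'
#' Draws `n_timepoints` i.i.d. rows from a zero-mean multivariate Gaussian
#' whose covariance is the group's implied covariance (optionally modulated
#' by subject-specific nodal gains).
#'
#' @inheritParams implied_covariance
#' @param n_timepoints number of timepoints (rows).
#' @param seed integer seed; deterministic given the seed.
#' @param subject_id subject identifier stored with the series.
#' @return a `roi_timeseries` object: list with `subject_id`, `data`
#'   (T x R matrix) and `roi_labels`.
#' @export
sample_subject_timeseries <- function(network, group, n_timepoints,
                                      noise_sd = 0, seed = NULL,
                                      subject_id = "sub_001",
                                      subject_gains = NULL) {
  stopifnot(group %in% c(0, 1))
  assert_scalar_number(n_timepoints, "n_timepoints", lower = 2)
  sigma <- implied_covariance(network, group, noise_sd, subject_gains)
  x <- with_seed(seed, MASS::mvrnorm(n_timepoints, mu = rep(0, nrow(sigma)),
                                     Sigma = sigma))
  colnames(x) <- network$roi_labels
  roi_timeseries(subject_id, x, network$roi_labels)
}

#' Cohort-generation settings
#'
#' Bundles the knobs of the synthetic-cohort generator. Defaults define the
#' package's desk-scale study conditions: two groups of 60 subjects, 150
#' timepoints, and an analytic/holistic-style score linearly coupled to a
#' few true nodal metrics plus noise.
#'
#' @param n_per_group subjects per group.
#' @param n_timepoints timepoints per subject.
#' @param noise_sd observation noise SD added on the covariance diagonal.
#' @param subject_sd SD of the lognormal per-node gains that make each
#'   subject's generating network an individual variation on the group
#'   network; `0` gives every subject the group covariance exactly.
#' @param phenotype_weights data frame with columns `node` (index), `metric`
#'   (`"degree"` or `"efficiency"`) and `weight`: linear coupling of the
#'   style score to the subject's *true* (generating-network) nodal AUC
#'   metrics, standardised across the cohort. Empty data frame = no
#'   coupling.
#' @param phenotype_noise_sd SD of the Gaussian noise on the style score
#'   (the coupled metrics are standardised, so this is in effect-size
#'   units).
#' @param covariate_confounding named list of additive group-0 shifts for
#'   `age` (years), `sex` (probability shift) and `motion` (scalar);
#'   zeros remove confounding.
#' @param sparsity numeric triple `(min, max, step)` of the sparsity sweep
#'   used to compute the true generating-network metrics.
#' @param seed default seed consumed by [generate_cohort()].
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 60, n_timepoints = 150, noise_sd = 0.5,
                        subject_sd = 0.3,
                        phenotype_weights = empty_phenotype_weights(),
                        phenotype_noise_sd = 2,
                        covariate_confounding = list(age = 9, sex = 0.15,
                                                     motion = 0.05),
                        sparsity = c(0.10, 0.30, 0.01), seed = NULL) {
  assert_scalar_number(n_per_group, "n_per_group", lower = 2)
  assert_scalar_number(n_timepoints, "n_timepoints", lower = 2)
  assert_scalar_number(noise_sd, "noise_sd")
  assert_scalar_number(subject_sd, "subject_sd", lower = 0)
  assert_scalar_number(phenotype_noise_sd, "phenotype_noise_sd")
  if (noise_sd <= 0) stopf("`noise_sd` must be > 0")
  if (phenotype_noise_sd <= 0) stopf("`phenotype_noise_sd` must be > 0")
  stopifnot(is.data.frame(phenotype_weights),
            all(c("node", "metric", "weight") %in% names(phenotype_weights)),
            all(phenotype_weights$metric %in% c("degree", "efficiency")))
  structure(list(n_per_group = as.integer(n_per_group),
                 n_timepoints = as.integer(n_timepoints),
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 phenotype_weights = phenotype_weights,
                 phenotype_noise_sd = phenotype_noise_sd,
                 covariate_confounding = covariate_confounding,
                 sparsity = sparsity, seed = seed),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
empty_phenotype_weights <- function() {
  data.frame(node = integer(0), metric = character(0), weight = numeric(0))
}

#' Phenotype-coupling table used by the package's default study conditions
#'
#' Couples the style score positively to the degree of two nodes,
#' negatively to the degree of a third, and positively to the efficiency of
#' a fourth, exercising both metric families and both correlation signs.
#'
#' @param nodes four node indices.
#' @param weight absolute coupling weight per metric (metrics are
#'   standardised before weighting).
#' @return a phenotype-weights data frame.
#' @export
default_phenotype_weights <- function(nodes = c(1L, 3L, 7L, 15L),
                                      weight = 1) {
  stopifnot(length(nodes) == 4)
  data.frame(node = as.integer(nodes),
             metric = c("degree", "degree", "degree", "efficiency"),
             weight = weight * c(1, 1, -1, 1))
}

#' Generate a two-group synthetic cohort
#'
#' For each subject: draw lognormal nodal gains, form the subject's
#' generating network from the group weights, sample the ROI time series,
#' and compute the subject's *true* nodal AUC metrics by running the actual
#' graph pipeline (negative zeroing, sparsity sweep, AUC) on the
#' generating-network correlation matrix. The style score (`ahs`) is a
#' weighted sum of standardised true metrics plus Gaussian noise; group-
#' confounded age, sex, motion and a site factor complete the phenotype
#' table.
#'
#' @param spec a [cohort_spec()].
#' @param network a [make_ground_truth()] network.
#' @param seed integer seed (defaults to `spec$seed`); the whole dataset is
#'   deterministic given (spec, network, seed).
#' @param groups which groups to generate: `0:1` (default) for a two-group
#'   cohort, or a single group for a one-sample (e.g. scored-only) study.
#' @return a `cohort_dataset`: list with `timeseries` (list of
#'   `roi_timeseries`), `phenotypes` (data frame with columns `subject_id`,
#'   `group`, `age`, `sex`, `motion`, `site`, `ahs`) and `truth`
#'   (generating parameters plus the true metric matrices).
#' @export
generate_cohort <- function(spec, network, seed = spec$seed, groups = 0:1) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(network, "ground_truth_network"),
            all(groups %in% 0:1), !anyDuplicated(groups))
  pw <- spec$phenotype_weights
  if (nrow(pw) && (any(pw$node < 1L) || any(pw$node > network$n_nodes))) {
    stopf("phenotype_weights reference nodes outside 1..%d", network$n_nodes)
  }
  if (spec$n_timepoints <= network$n_nodes) {
    warnf("n_timepoints (%d) <= n_nodes (%d); correlation estimates will be noisy",
          spec$n_timepoints, network$n_nodes)
  }
  r <- network$n_nodes
  n <- length(groups) * spec$n_per_group
  group <- rep(sort(groups), each = spec$n_per_group)
  ids <- sprintf("sub_%03d", seq_len(n))
  grid <- sparsity_grid(spec$sparsity[1], spec$sparsity[2], spec$sparsity[3])

  with_seed(seed, {
    ts_list <- vector("list", n)
    true_deg <- matrix(NA_real_, n, r, dimnames = list(ids, network$roi_labels))
    true_eff <- true_deg
    for (s in seq_len(n)) {
      gains <- if (spec$subject_sd > 0) {
        exp(stats::rnorm(r, -spec$subject_sd^2 / 2, spec$subject_sd))
      } else NULL
      sigma <- implied_covariance(network, group[s], spec$noise_sd, gains)
      x <- MASS::mvrnorm(spec$n_timepoints, mu = rep(0, r), Sigma = sigma)
      colnames(x) <- network$roi_labels
      ts_list[[s]] <- roi_timeseries(ids[s], x, network$roi_labels)
      if (nrow(pw)) {
        # true metrics from the generating correlation structure
        gen_corr <- correlation_matrix(stats::cov2cor(sigma), network$roi_labels)
        stack <- threshold_sweep(zero_negatives(gen_corr), spec$sparsity[1],
                                 spec$sparsity[2], spec$sparsity[3])
        m <- subject_metrics(stack, subject_id = ids[s])
        true_deg[s, ] <- m$degree_auc
        true_eff[s, ] <- m$efficiency_auc
      }
    }

    ahs <- stats::rnorm(n, 0, spec$phenotype_noise_sd)
    if (nrow(pw)) {
      for (i in seq_len(nrow(pw))) {
        v <- if (pw$metric[i] == "degree") true_deg[, pw$node[i]]
             else true_eff[, pw$node[i]]
        # standardised within group: the score couples to the subject's
        # deviation from their group's metric profile, so the coupling
        # strength does not depend on the cohort's group composition
        z <- v
        for (g in unique(group)) {
          idx <- group == g
          z[idx] <- (v[idx] - mean(v[idx])) / stats::sd(v[idx])
        }
        ahs <- ahs + pw$weight[i] * z
      }
    }

    cc <- spec$covariate_confounding
    west <- as.numeric(group == 0)
    age <- stats::rnorm(n, 22, 3) + (cc$age %||% 0) * west
    p_sex <- pmin(pmax(0.3 + (cc$sex %||% 0) * west, 0.01), 0.99)
    sex <- stats::rbinom(n, 1, p_sex)
    motion <- stats::rlnorm(n, -2, 0.4) + (cc$motion %||% 0) * west
    site <- sample.int(3L, n, replace = TRUE, prob = c(0.4, 0.3, 0.3))

    phenotypes <- data.frame(subject_id = ids, group = group, age = age,
                             sex = sex, motion = motion, site = site,
                             ahs = ahs, stringsAsFactors = FALSE)
    structure(list(timeseries = ts_list, phenotypes = phenotypes,
                   truth = list(network = network, spec = spec, seed = seed,
                                true_degree_auc = true_deg,
                                true_efficiency_auc = true_eff,
                                sparsity_grid = grid)),
              class = "cohort_dataset")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
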
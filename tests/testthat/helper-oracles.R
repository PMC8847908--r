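# Independent oracles and fixture builders shared across the suite.

# Floyd-Warshall all-pairs shortest paths; independent of the package's
# frontier-expansion BFS.
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

random_adjacency <- function(n, p) {
  a <- matrix(stats::runif(n * n) < p, n, n)
  a[lower.tri(a, diag = TRUE)] <- FALSE
  a | t(a)
}

# canonical demo study conditions used across tests
demo_network <- function(delta = 1.2) {
  make_ground_truth(20, 0.3, effect_nodes = c(1L, 3L, 7L, 15L),
                    effect_delta = delta, seed = 8)
}

demo_effect_rois <- function() sprintf("ROI_%02d", c(1, 3, 7, 15))

demo_selection <- function() {
  data.frame(node = demo_effect_rois(),
             metric = c("degree", "degree", "degree", "efficiency"),
             sign = c(1, 1, -1, 1), stringsAsFactors = FALSE)
}

# small cohort + metrics shared by several test files; built once per run
.test_cache <- new.env(parent = emptyenv())

small_coupled_cohort <- function() {
  if (is.null(.test_cache$coh)) {
    net <- demo_network()
    spec <- cohort_spec(n_per_group = 40, n_timepoints = 120,
                        phenotype_weights = default_phenotype_weights())
    .test_cache$coh <- generate_cohort(spec, net, seed = 421)
    .test_cache$metrics <- cohort_metrics(.test_cache$coh$timeseries)
  }
  list(cohort = .test_cache$coh, metrics = .test_cache$metrics)
}
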
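path_graph <- function(n) {
  a <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- TRUE
  a
}

complete_graph <- function(n) {
  a <- matrix(TRUE, n, n)
  diag(a) <- FALSE
  a
}

test_that("degree equals row sums and twice the edge count", {
  expect_equal(nodal_degree(complete_graph(4)), rep(3, 4))
  expect_equal(nodal_degree(matrix(FALSE, 3, 3)), rep(0, 3))
  set.seed(1)
  for (rep in 1:10) {
    a <- random_adjacency(10, 0.3)
    d <- nodal_degree(a)
    expect_equal(d, apply(a, 1, sum))
    expect_equal(sum(d), 2 * sum(a[upper.tri(a)]))
  }
})

test_that("BFS distances agree with Floyd-Warshall and igraph on random graphs", {
  set.seed(2)
  library(igraph)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    a <- random_adjacency(n, stats::runif(1, 0.1, 0.7))
    d <- shortest_paths_matrix(a)
    expect_identical(unname(d), floyd_warshall(a))
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_identical(unname(d),
                     unname(igraph::distances(g, algorithm = "unweighted")))
  }
})

test_that("distances handle paths and disconnected components", {
  a <- path_graph(3)
  d <- shortest_paths_matrix(a)
  expect_equal(d[1, 3], 2)
  two_comp <- matrix(FALSE, 4, 4)
  two_comp[1, 2] <- two_comp[2, 1] <- TRUE
  two_comp[3, 4] <- two_comp[4, 3] <- TRUE
  d2 <- shortest_paths_matrix(two_comp)
  expect_true(is.infinite(d2[1, 3]) && is.infinite(d2[2, 4]))
  expect_equal(d2[1, 2], 1)
})

test_that("nodal global efficiency matches analytic values on canonical graphs", {
  expect_equal(nodal_global_efficiency(complete_graph(5)), rep(1, 5))
  # path 1-2-3: ends (1 + 1/2)/2, middle (1 + 1)/2
  expect_equal(nodal_global_efficiency(path_graph(3)), c(0.75, 1, 0.75))
  # star on 4 nodes: hub 1, leaves (1 + 1/2 + 1/2)/3
  star <- matrix(FALSE, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- TRUE
  expect_equal(nodal_global_efficiency(star), c(1, 2/3, 2/3, 2/3))
  # isolated node contributes and receives zeros
  iso <- matrix(FALSE, 3, 3)
  iso[1, 2] <- iso[2, 1] <- TRUE
  expect_equal(nodal_global_efficiency(iso), c(0.5, 0.5, 0))
  expect_error(nodal_global_efficiency(matrix(FALSE, 1, 1)), ">= 2")
})

test_that("adding an edge never decreases degree or efficiency", {
  set.seed(3)
  for (rep in 1:15) {
    a <- random_adjacency(9, 0.25)
    absent <- which(!a & upper.tri(a), arr.ind = TRUE)
    if (!nrow(absent)) next
    pick <- absent[sample(nrow(absent), 1), ]
    b <- a
    b[pick[1], pick[2]] <- b[pick[2], pick[1]] <- TRUE
    expect_true(all(nodal_degree(b) >= nodal_degree(a)))
    expect_true(all(nodal_global_efficiency(b) >=
                      nodal_global_efficiency(a) - 1e-12))
    expect_true(all(nodal_global_efficiency(b) <= 1))
  }
})

test_that("trapezoid AUC is exact for constant and linear profiles", {
  grid <- seq(0.10, 0.30, by = 0.01)
  const <- matrix(3.7, 4, length(grid))
  expect_equal(metric_auc(const, grid), rep(3.7 * 0.2, 4), tolerance = 1e-10)
  # values linear in S: v = a + b*S integrates to a*w + b*(smax^2-smin^2)/2
  a <- c(1, -2, 0.5); b <- c(4, 1, -3)
  lin <- outer(a, rep(1, length(grid))) + outer(b, grid)
  expect_equal(metric_auc(lin, grid),
               a * 0.2 + b * (0.30^2 - 0.10^2) / 2, tolerance = 1e-10)
  expect_error(metric_auc(matrix(1, 2, 1), 0.1), ">= 2")
  expect_error(metric_auc(matrix(1, 2, 3), c(0.1, 0.2)), "columns")
})

test_that("subject metrics compose the per-slice operations", {
  # identical complete-graph slices: degree AUC = (R-1)*width, efficiency = width
  full <- matrix(TRUE, 4, 4); diag(full) <- FALSE
  dimnames(full) <- list(sprintf("ROI_%02d", 1:4), sprintf("ROI_%02d", 1:4))
  st <- structure(list(adjacency = array(full, c(4, 4, 2),
                                         dimnames = c(dimnames(full), list(NULL))),
                       sparsity_grid = c(0.10, 0.30),
                       roi_labels = rownames(full), n_edges = c(6L, 6L)),
                  class = "binary_graph_stack")
  m <- subject_metrics(st, "s", keep_per_threshold = TRUE)
  expect_equal(unname(m$degree_auc), rep(3 * 0.2, 4))
  expect_equal(unname(m$efficiency_auc), rep(0.2, 4))
  # empty-graph stack: all metrics zero
  st$adjacency[] <- FALSE
  m0 <- subject_metrics(st, "s")
  expect_true(all(m0$degree_auc == 0) && all(m0$efficiency_auc == 0))
  # random stack equals the composition of independently tested operations
  set.seed(4)
  x <- matrix(rnorm(120 * 10), 120, 10)
  corr2 <- zero_negatives(compute_correlation(roi_timeseries("s", x)))
  st2 <- threshold_sweep(corr2, 0.1, 0.3, 0.05)
  m2 <- subject_metrics(st2, "s")
  deg <- sapply(seq_along(st2$sparsity_grid),
                function(k) nodal_degree(st2$adjacency[, , k]))
  eff <- sapply(seq_along(st2$sparsity_grid),
                function(k) nodal_global_efficiency(st2$adjacency[, , k]))
  expect_equal(unname(m2$degree_auc), metric_auc(deg, st2$sparsity_grid))
  expect_equal(unname(m2$efficiency_auc), metric_auc(eff, st2$sparsity_grid))
  expect_true(all(eff >= 0 & eff <= 1))
})
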
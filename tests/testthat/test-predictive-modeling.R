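test_that("direction unification flips exactly the negative-sign columns", {
  set.seed(41)
  m <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_identical(unify_directions(m, c(1, 1, 1)), m)
  u <- unify_directions(m, c(1, -1, 1))
  expect_identical(u[, 2], -m[, 2])
  y <- rnorm(20)
  expect_equal(stats::cor(u[, 2], y), -stats::cor(m[, 2], y))
  expect_error(unify_directions(m, c(1, 0, 1)), "zero not allowed")
  # post-unification every member correlates nonnegatively with the outcome
  signs <- ifelse(as.vector(stats::cor(m, y)) >= 0, 1, -1)
  u2 <- unify_directions(m, signs)
  expect_true(all(stats::cor(u2, y) >= 0))
})

test_that("composites are means of sign-unified members", {
  set.seed(42)
  ids <- sprintf("s%d", 1:15)
  deg <- matrix(rnorm(45), 15, 3, dimnames = list(ids, c("n1", "n2", "n3")))
  eff <- matrix(rnorm(45), 15, 3, dimnames = list(ids, c("n1", "n2", "n3")))
  metrics <- list(degree_auc = deg, efficiency_auc = eff)
  sel <- data.frame(node = c("n1", "n3", "n2"),
                    metric = c("degree", "degree", "efficiency"),
                    sign = c(1, -1, 1))
  comp <- build_composites(metrics, sel)
  expect_equal(comp$t_deg, rowMeans(cbind(deg[, "n1"], -deg[, "n3"])))
  expect_equal(comp$t_eg, eff[, "n2"])  # single member: composite is the metric
  sel1 <- data.frame(node = "n2", metric = "degree", sign = 1)
  expect_equal(build_composites(metrics, sel1)$t_deg, deg[, "n2"])
  expect_null(build_composites(metrics, sel1)$t_eg)
  expect_error(build_composites(metrics,
                                data.frame(node = "zz", metric = "degree",
                                           sign = 1)),
               "missing")
})

test_that("k-fold regression covers every subject once and nails a noiseless signal", {
  set.seed(43)
  n <- 80
  x <- cbind(rnorm(n), rnorm(n))
  y <- 2 + 1.5 * x[, 1] - 0.5 * x[, 2]
  out <- kfold_predict_continuous(x, y, k = 10, seed = 7)
  expect_gt(out$estimate, 0.999)
  expect_equal(sort(unique(out$folds)), 1:10)
  expect_equal(tabulate(out$folds), rep(8, 10))  # each subject predicted once
  out2 <- kfold_predict_continuous(x, y, k = 10, seed = 7)
  expect_identical(out$predicted, out2$predicted)
  expect_error(kfold_predict_continuous(x[1:15, ], y[1:15], k = 10), "2k")
})

test_that("cross-validated r on pure noise is centred at or below zero", {
  set.seed(44)
  rs <- vapply(1:50, function(i) {
    x <- cbind(rnorm(300), rnorm(300))
    kfold_predict_continuous(x, rnorm(300), k = 10)$estimate
  }, numeric(1))
  expect_lte(stats::median(rs), 0)  # CV null bias is nonpositive
  expect_lt(mean(rs), 0.05)        # and no positive drift
  # the null r is heavy-tailed (scale-invariance of correlation lets tiny
  # fold-mean differences produce sizable |r|), but stays well below any
  # genuine-signal estimate at this n
  expect_true(all(abs(rs) < 0.5))
})

test_that("classification is stratified, perfect under huge separation, chance under shuffling", {
  set.seed(45)
  n <- 120
  labels <- rep(0:1, each = n / 2)
  x <- cbind(rnorm(n) + 10 * labels, rnorm(n))
  out <- kfold_classify(x, labels, k = 10, seed = 8)
  expect_equal(out$estimate, 1)
  expect_equal(unname(out$per_group_accuracy), c(1, 1))
  for (f in 1:10) expect_equal(length(unique(labels[out$folds != f])), 2)
  accs <- vapply(1:20, function(i) {
    kfold_classify(x, sample(labels), k = 10)$estimate
  }, numeric(1))
  expect_gt(mean(accs), 0.40)
  expect_lt(mean(accs), 0.60)
})

test_that("permutation calibration bookkeeping follows the sorted-position rule", {
  set.seed(46)
  vals <- rnorm(1000)
  i <- 0
  proc <- function(y) { i <<- i + 1; vals[i] }
  res <- permutation_calibrate(proc, rnorm(50), observed = 0.5,
                               n_perm = 1000, seed = 9)
  expect_length(res$null_distribution, 1000)
  srt <- sort(vals)
  expect_equal(unname(res$ci95), c(srt[25], srt[975]))
  expect_equal(res$p_perm, (1 + sum(vals >= 0.5)) / 1001)
  expect_identical(res$significant, 0.5 > srt[975])
  obs_inside <- srt[500]
  i <- 0
  expect_false(permutation_calibrate(proc, rnorm(50), observed = obs_inside,
                                     n_perm = 1000, seed = 9)$significant)
  expect_error(permutation_calibrate(proc, rnorm(10), 1, n_perm = 39),
               ">= 40")
})

test_that("null accuracy distribution is centred near one half on balanced labels", {
  set.seed(47)
  n <- 80
  labels <- rep(0:1, each = n / 2)
  x <- cbind(rnorm(n), rnorm(n))
  res <- permutation_calibrate(
    function(lab) kfold_classify(x, lab, k = 10)$estimate,
    labels, observed = 0.5, n_perm = 60, seed = 10)
  expect_lt(abs(mean(res$null_distribution) - 0.5), 0.06)
})

test_that("CPM selects strong metrics in every fold and null selections track alpha", {
  set.seed(48)
  n <- 150; r <- 20
  ids <- sprintf("s%03d", 1:n)
  nm <- sprintf("ROI_%02d", 1:r)
  deg <- matrix(rnorm(n * r), n, r, dimnames = list(ids, nm))
  eff <- matrix(rnorm(n * r), n, r, dimnames = list(ids, nm))
  y <- deg[, 2] + deg[, 5] - deg[, 9] + eff[, 12] + eff[, 17] +
    rnorm(n, sd = 0.8)
  out <- cpm_predict(list(degree_auc = deg, efficiency_auc = eff), y,
                     k = 10, alpha = 0.05, seed = 11)
  strong <- c("degree:ROI_02", "degree:ROI_05", "degree:ROI_09",
              "efficiency:ROI_12", "efficiency:ROI_17")
  stab <- stability_select(out$fold_selections, min_count = 10)
  expect_true(all(strong %in% stab$item))
  expect_gt(out$estimate, 0.5)
  # null outcome: expected selections per fold ~ alpha * n_metrics
  y0 <- rnorm(n)
  out0 <- suppressWarnings(  # folds with no null selections are expected
    cpm_predict(list(degree_auc = deg, efficiency_auc = eff), y0,
                k = 10, alpha = 0.05, seed = 12))
  mean_sel <- mean(lengths(out0$fold_selections))
  expect_lt(abs(mean_sel - 0.05 * 2 * r), 3)
})

test_that("stability selection is an exact count filter", {
  sets <- c(rep(list(c("degree:a", "degree:b")), 9),
            list(c("degree:a", "efficiency:c")))
  res <- stability_select(sets, min_count = 10)
  expect_equal(res$item, "degree:a")
  expect_equal(res$count, 10)
  res9 <- stability_select(sets, min_count = 9)
  expect_setequal(res9$item, c("degree:a", "degree:b"))
  expect_equal(nrow(stability_select(list(character(0)), 1)), 0)
})

test_that("cross-sample classification with informative composites beats its null", {
  d <- small_coupled_cohort()
  coh <- d$cohort; m <- d$metrics
  labels <- coh$phenotypes$group
  out <- cross_sample_classify(demo_selection(), m, labels, k = 10, seed = 13)
  perm <- permutation_calibrate(
    function(lab) {
      comp <- build_composites(m, demo_selection())
      kfold_classify(cbind(comp$t_deg, comp$t_eg), lab, k = 10)$estimate
    }, labels, out$estimate, n_perm = 60, seed = 14)
  expect_gt(out$estimate, perm$ci95[["upper"]])
  expect_named(out$per_group_accuracy, c("0", "1"))
  # pure-noise selection stays within its null band
  set.seed(49)
  noise <- list(degree_auc = matrix(rnorm(nrow(m$degree_auc) * 4),
                                    ncol = 4,
                                    dimnames = list(rownames(m$degree_auc),
                                                    paste0("x", 1:4))),
                efficiency_auc = matrix(rnorm(nrow(m$degree_auc) * 4),
                                        ncol = 4,
                                        dimnames = list(rownames(m$degree_auc),
                                                        paste0("x", 1:4))))
  sel_noise <- data.frame(node = c("x1", "x2"), metric = c("degree", "efficiency"),
                          sign = c(1, 1))
  out0 <- cross_sample_classify(sel_noise, noise, labels, k = 10, seed = 15)
  expect_lt(out0$estimate, 0.65)
})
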
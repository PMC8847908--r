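test_that("ground-truth network has the requested density, symmetry and determinism", {
  net <- make_ground_truth(20, 0.3, seed = 1)
  w <- net$base_weights
  expect_identical(w, t(w))
  expect_true(all(diag(w) == 0))
  frac <- sum(w[upper.tri(w)] > 0) / choose(20, 2)
  expect_lt(abs(frac - 0.3), 0.05)
  net2 <- make_ground_truth(20, 0.3, seed = 1)
  expect_identical(net$base_weights, net2$base_weights)
  # complete graph with equal weights: all off-diagonal entries equal
  net3 <- make_ground_truth(5, 0.99, seed = 2, weight_range = c(0.4, 0.4))
  off <- net3$base_weights[upper.tri(net3$base_weights)]
  expect_true(all(off == 0.4))
})

test_that("zero effect delta makes the two group covariances identical", {
  net <- make_ground_truth(15, 0.3, effect_nodes = c(2L, 5L), effect_delta = 0,
                           seed = 3)
  expect_identical(implied_covariance(net, 0), implied_covariance(net, 1))
  net_d <- make_ground_truth(15, 0.3, effect_nodes = c(2L, 5L),
                             effect_delta = 0.5, seed = 3)
  s0 <- implied_covariance(net_d, 0)
  s1 <- implied_covariance(net_d, 1)
  expect_identical(diag(s0), diag(s1))  # shared ridge
  # only edges incident to effect nodes change
  changed <- which(s0 != s1, arr.ind = TRUE)
  expect_true(all(changed[, 1] %in% c(2, 5) | changed[, 2] %in% c(2, 5)))
})

test_that("sampled time series converge to the generating correlation", {
  net <- make_ground_truth(8, 0.4, seed = 4)
  ts <- sample_subject_timeseries(net, group = 0, n_timepoints = 20000,
                                  noise_sd = 0.3, seed = 5)
  emp <- stats::cor(ts$data)
  gen <- stats::cov2cor(implied_covariance(net, 0, noise_sd = 0.3))
  expect_lt(max(abs(emp - gen)), 0.05)
})

test_that("time-series sampling is deterministic and independent when weights vanish", {
  net <- make_ground_truth(6, 0.3, seed = 6)
  net$base_weights[] <- 0
  net$lambda <- 0.01
  ts1 <- sample_subject_timeseries(net, 0, 500, noise_sd = 2, seed = 7)
  ts2 <- sample_subject_timeseries(net, 0, 500, noise_sd = 2, seed = 7)
  expect_identical(ts1$data, ts2$data)
  offdiag <- stats::cor(ts1$data)[upper.tri(diag(6))]
  expect_lt(max(abs(offdiag)), 0.2)  # ~N(0, 1/sqrt(500)) scale
})

test_that("cohort generation is reproducible and validates its inputs", {
  net <- demo_network()
  spec <- cohort_spec(n_per_group = 5, n_timepoints = 60)
  c1 <- generate_cohort(spec, net, seed = 10)
  c2 <- generate_cohort(spec, net, seed = 10)
  expect_identical(c1$timeseries[[3]]$data, c2$timeseries[[3]]$data)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_equal(nrow(c1$phenotypes), 10)
  expect_false(anyDuplicated(c1$phenotypes$subject_id) > 0)

  bad <- cohort_spec(n_per_group = 5, n_timepoints = 60,
                     phenotype_weights = data.frame(
                       node = 99L, metric = "degree", weight = 1))
  expect_error(generate_cohort(bad, net, seed = 1), "outside")
  expect_warning(
    generate_cohort(cohort_spec(n_per_group = 2, n_timepoints = 15), net,
                    seed = 1),
    "noisy")
})

test_that("null coupling leaves the score unrelated to metrics and covariate balance holds", {
  net <- demo_network(delta = 0)
  spec <- cohort_spec(n_per_group = 150, n_timepoints = 60,
                      covariate_confounding = list(age = 0, sex = 0, motion = 0))
  coh <- generate_cohort(spec, net, seed = 11)
  ph <- coh$phenotypes
  # no confounding: group means of age and motion differ only by noise
  expect_gt(stats::t.test(age ~ group, data = ph)$p.value, 0.01)
  expect_gt(stats::t.test(motion ~ group, data = ph)$p.value, 0.01)
  # ahs is pure noise: correlation with any measured metric is small
  m <- cohort_metrics(coh$timeseries[1:80], s_min = 0.1, s_max = 0.3, step = 0.05)
  rs <- abs(stats::cor(m$degree_auc, ph$ahs[1:80]))
  expect_lt(mean(rs), 0.15)
})

test_that("confounded covariates shift the unscored group as configured", {
  net <- demo_network(delta = 0)
  spec <- cohort_spec(n_per_group = 300, n_timepoints = 40,
                      covariate_confounding = list(age = 9, sex = 0.15,
                                                   motion = 0.05))
  coh <- generate_cohort(spec, net, seed = 12)
  ph <- coh$phenotypes
  d_age <- mean(ph$age[ph$group == 0]) - mean(ph$age[ph$group == 1])
  expect_lt(abs(d_age - 9), 1)
  d_mot <- mean(ph$motion[ph$group == 0]) - mean(ph$motion[ph$group == 1])
  expect_lt(abs(d_mot - 0.05), 0.03)
})

test_that("planted effect nodes rank top-4 by multivariate F in the identifiable regime", {
  # documented operating point: low individual variability, large n
  net <- demo_network(delta = 1.0)
  spec <- cohort_spec(n_per_group = 500, subject_sd = 0.1)
  hits <- 0
  n_rep <- 5
  for (r in seq_len(n_rep)) {
    coh <- generate_cohort(spec, net, seed = 900 + r)
    m <- cohort_metrics(coh$timeseries)
    sc <- screen_nodes(m, coh$phenotypes)
    top4 <- sc$stats$node[order(-sc$stats$F_mancova)][1:4]
    hits <- hits + all(demo_effect_rois() %in% top4)
  }
  expect_gte(hits / n_rep, 0.8)
})
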
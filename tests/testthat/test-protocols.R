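test_that("estimate aggregation drops the extremes and averages the rest", {
  expect_equal(aggregate_estimates(rep(1.4, 6)), 1.4)
  expect_equal(aggregate_estimates(1:6), mean(2:5))
  expect_equal(aggregate_estimates(c(3, 1, 6, 2, 5, 4)), 3.5)
  expect_error(aggregate_estimates(c(1, 2)))
})

test_that("suppression index is the largest-minus-smallest log threshold", {
  expect_equal(spatial_suppression_index(rep(1.3, 4)), 0)
  expect_equal(spatial_suppression_index(c(1, 1.5, 1.8, 2)), 1)
  expect_equal(spatial_suppression_index(c(1.2, 1.3, 1.5, 1.6)), 0.4)
})

test_that("the spatial-suppression session recovers known thresholds", {
  pop <- sample_population(population_spec(n_subjects = 2, seed = 6))
  obs <- pop$observers[1, ]
  truth <- as.numeric(obs[paste0("mdd_log_threshold_", 1:4)])
  set.seed(61)
  reps <- replicate(25, run_spatial_suppression(obs)$thresholds)
  expect_equal(rowMeans(reps), truth, tolerance = 0.05)
  expect_error(run_spatial_suppression(obs, blocks = 1, estimates_per_block = 2),
               "at least 6")
})

test_that("difference limen arithmetic and sign behave", {
  # DL = (x75 - x25) / 2 directly
  expect_equal((60 - 40) / 2, 10)
  pop <- sample_population(population_spec(n_subjects = 2, seed = 14))
  obs <- pop$observers[1, ]
  set.seed(15)
  res <- replicate(60, {
    r <- run_duration_discrimination(obs, "empty")
    c(r$x25, r$x75, r$dl)
  })
  expect_true(all(res[3, ] >= 0 | res[2, ] < res[1, ]))
  # symmetric observer: both series sit about equally far from the standard
  expect_equal(mean(res[2, ] - 50), mean(50 - res[1, ]), tolerance = 2.5)
  # converged difference tracks the 75% point of the psychometric function
  expect_equal(mean(pf_logistic_delta(res[2, ] - 50, obs$dd_jnd_empty)),
               0.75, tolerance = 0.03)
})

test_that("the dispersion index identifies a perfect and a guessing observer", {
  obs <- list(mdd_log_threshold_1 = 1, mdd_log_threshold_2 = 1,
              mdd_log_threshold_3 = 1, mdd_log_threshold_4 = 1,
              dd_jnd_empty = 10, dd_jnd_filled = 10, tg_sd = 0,
              rp_jnd = 40, psychometric_slope = 3.5, lapse_rate = 0)
  set.seed(3)
  perfect <- run_temporal_generalization(obs)
  expect_equal(perfect$index, 1)
  expect_equal(perfect$inverted, 0)
  expect_false(perfect$flagged)

  # a guessing observer (flat kernel) has expected index 1/7
  obs$tg_sd <- 1e9; obs$lapse_rate <- 0.01
  set.seed(9)
  idx <- replicate(300, run_temporal_generalization(obs)$index)
  expect_equal(mean(idx), 1 / 7, tolerance = 0.01)

  # no yes responses at all: flagged and scored as worst
  obs$tg_sd <- 0; obs$lapse_rate <- 0
  obs2 <- obs
  set.seed(11)
  res <- with_mocked_bindings(
    run_temporal_generalization(obs2),
    respond_generalization = function(...) FALSE,
    .package = "trpsupp")
  expect_true(res$flagged)
  expect_equal(res$index, 0)
  expect_equal(res$inverted, 1)
})

test_that("rhythm session starts at 20 ms and converges to the 75% point", {
  pop <- sample_population(population_spec(n_subjects = 2, seed = 23))
  obs <- pop$observers[1, ]
  set.seed(24)
  res <- run_rhythm_perception(obs)
  expect_equal(res$series[[1]]$levels[1], 20)
  expect_equal(res$series[[2]]$levels[1], 20)
  expect_equal(res$threshold, mean(res$series_thresholds))
  # two series thresholds 40 and 60 average to 50
  expect_equal(mean(c(40, 60)), 50)
  # converged level sits near the 75% point for an observer whose
  # threshold is reachable from the 20 ms start within 32 trials
  obs$rp_jnd <- 30
  set.seed(25)
  thr <- replicate(40, run_rhythm_perception(obs)$threshold)
  expect_equal(mean(pf_logistic_delta(thr, obs$rp_jnd)), 0.75,
               tolerance = 0.04)
})

test_that("composite scoring matches a hand-computed toy table", {
  set.seed(2)
  x <- matrix(rnorm(5 * 18, mean = 10, sd = 3), 5, 18)
  comp <- score_bis(x)
  # brute force: z-score each column, average each bundle
  z <- apply(x, 2, function(c) (c - mean(c)) / sd(c))
  expect_equal(comp$bis_capacity, rowMeans(z[, 1:6]), tolerance = 1e-12)
  expect_equal(comp$bis_speed, rowMeans(z[, 7:12]), tolerance = 1e-12)
  expect_equal(comp$bis_memory, rowMeans(z[, 13:18]), tolerance = 1e-12)
  expect_equal(colMeans(as.matrix(comp)), c(bis_capacity = 0, bis_speed = 0,
                                            bis_memory = 0), tolerance = 1e-12)
  x[, 4] <- 7
  expect_error(score_bis(x), "zero-variance")
})

test_that("the outlier screen removes exactly the planted high outlier once", {
  pop <- sample_population(population_spec(n_subjects = 60, seed = 41))
  meas <- simulate_measures(pop, mode = "measure")
  clean <- outlier_filter(meas)
  base <- clean$data
  # plant one subject far above the mean on one screened variable
  planted <- base
  m <- mean(planted$dl_empty); s <- sd(planted$dl_empty)
  planted$dl_empty[7] <- m + 5 * s
  res <- outlier_filter(planted)
  expect_equal(res$removed$subject, planted$subject[7])
  expect_equal(nrow(res$data), nrow(planted) - 1)
  expect_equal(res$log$variable, "dl_empty")
  # one-pass: values that become extreme only after removal are kept
  again <- outlier_filter(res$data)
  expect_lte(nrow(res$data) - nrow(again$data), nrow(res$data))
  # tiny samples are passed through with a warning
  expect_warning(outlier_filter(meas[1:2, ]), "skipped")
})

test_that("simulated measures carry the end-to-end ordering invariants", {
  pop <- sample_population(population_spec(n_subjects = 150, seed = 19))
  meas <- simulate_measures(pop, mode = "measure")
  mm <- colMeans(meas[paste0("mdd_", 1:4)])
  expect_true(all(diff(mm) > 0))
  expect_gt(mean(meas$si), 0)
  expect_true(all(meas$tg_index_raw >= 0 & meas$tg_index_raw <= 1))
  # deterministic given the same population and seed
  small <- sample_population(population_spec(n_subjects = 3, seed = 19))
  a <- simulate_measures(small, mode = "trial", seed = 5)
  b <- simulate_measures(small, mode = "trial", seed = 5)
  expect_identical(a, b)
})
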
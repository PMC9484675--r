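test_that("degenerate generator settings collapse the threshold profile", {
  spec <- population_spec(n_subjects = 20, ssi_sd = 0, mdd_noise_sd = 0,
                          si_mean = 0, seed = 8)
  pop <- sample_population(spec)
  m <- pop$observers
  expect_equal(m$mdd_log_threshold_1, m$mdd_log_threshold_2)
  expect_equal(m$mdd_log_threshold_1, m$mdd_log_threshold_3)
  expect_equal(m$mdd_log_threshold_1, m$mdd_log_threshold_4)
})

test_that("identity latent correlations produce near-zero sample correlations", {
  spec <- population_spec(n_subjects = 10000, latent_corr = diag(4) + 0,
                          seed = 21)
  dimnames(spec$latent_corr) <- dimnames(default_latent_corr())
  pop <- sample_population(spec)
  r <- cor(pop$latents[, c("trp", "ssc", "ssi", "g")])
  expect_true(all(abs(r[lower.tri(r)]) < 0.03))
})

test_that("noise-free threshold covariance matches its closed form", {
  spec <- population_spec(n_subjects = 50000, latent_corr = diag(4) + 0,
                          mdd_noise_sd = 0, seed = 13)
  dimnames(spec$latent_corr) <- dimnames(default_latent_corr())
  pop <- sample_population(spec)
  mdd <- as.matrix(pop$observers[paste0("mdd_log_threshold_", 1:4)])
  w <- 0:3
  # empirical latent moments make the check exact, not just asymptotic
  ssc <- pop$latents$ssc; ssi <- pop$latents$ssi
  expected <- spec$ssc_sd^2 * var(ssc) * outer(rep(1, 4), rep(1, 4)) +
    spec$ssi_sd^2 * var(ssi) * outer(w, w) +
    spec$ssc_sd * spec$ssi_sd * cov(ssc, ssi) *
      (outer(rep(1, 4), w) + outer(w, rep(1, 4)))
  expect_equal(unname(cov(mdd)), expected, tolerance = 1e-10)
})

test_that("population sampling is reproducible and validates its inputs", {
  spec <- population_spec(n_subjects = 30, seed = 99)
  a <- sample_population(spec)
  b <- sample_population(spec)
  expect_identical(a$observers, b$observers)
  expect_identical(a$bis_subtests, b$bis_subtests)

  bad <- default_latent_corr()
  bad[1, 2] <- bad[2, 1] <- 0.999
  bad[1, 3] <- bad[3, 1] <- -0.999
  bad[2, 3] <- bad[3, 2] <- 0.999
  expect_error(population_spec(latent_corr = bad), "positive semi-definite")
  expect_error(population_spec(n_subjects = 1), "n_subjects")
})

test_that("a stronger timing-intelligence path strengthens the observable correlation", {
  cors <- sapply(c(-0.1, -0.5, -0.9), function(b) {
    spec <- population_spec(n_subjects = 5000,
                            latent_corr = default_latent_corr(beta_trp_g = b),
                            seed = 77)
    pop <- sample_population(spec)
    meas <- simulate_measures(pop, mode = "measure")
    cor(meas$dl_filled, meas$bis_capacity)
  })
  expect_true(all(diff(cors) < 0))  # more negative path, more negative correlation
})

test_that("generator calibration puts the suppression index near its target", {
  pop <- sample_population(population_spec(n_subjects = 4000, seed = 5))
  meas <- simulate_measures(pop, mode = "measure")
  expect_equal(mean(meas$si), 0.29, tolerance = 0.02)
  expect_equal(mean(tg_expected_index(pop$observers$tg_sd)), 0.66,
               tolerance = 0.04)
})
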
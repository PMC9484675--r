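test_that("the analytic gradient matches finite differences on every matrix type", {
  set.seed(42)
  spec <- build_model("combined")
  S <- crossprod(matrix(rnorm(22 * 11), 22, 11)) / 21 + diag(11) * 0.5
  par <- trpsupp:::sem_start(spec, S)
  ldS <- determinant(S, TRUE)$modulus[1]
  g <- trpsupp:::sem_fml_grad(spec, par, S)
  gn <- vapply(seq_along(par), function(k) {
    h <- 1e-6; pp <- par
    pp[k] <- pp[k] + h
    fp <- trpsupp:::sem_fml(spec, pp, S, ldS)
    pp[k] <- pp[k] - 2 * h
    fm <- trpsupp:::sem_fml(spec, pp, S, ldS)
    (fp - fm) / (2 * h)
  }, numeric(1))
  expect_equal(g, gn, tolerance = 1e-6)
})

test_that("fitting the model to its own implied covariance recovers the truth", {
  set.seed(1)
  for (rep in 1:3) {
    mod <- random_factor_model(p = 4)
    spec <- mod$spec
    fit <- fit_ml(spec, mod$sigma0, 100)
    expect_lt(fit$F_ml, 1e-10)
    lam_hat <- fit$matrices$lambda[, 1]
    # loadings identified up to a global sign flip
    if (sum(lam_hat) < 0) lam_hat <- -lam_hat
    expect_equal(unname(lam_hat), mod$lam_true, tolerance = 1e-4)
    expect_equal(unname(diag(fit$matrices$theta)), mod$th_true,
                 tolerance = 1e-4)
  }
})

test_that("a three-indicator one-factor model is exactly identified", {
  fit <- fit_ml(build_model("g_cfa"), ref_bis_cor(), 273)
  expect_equal(fit$df, 0)
  expect_lt(fit$F_ml, 1e-10)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$rmsea, 0)
  expect_true(is.na(fit$p_value))
})

test_that("fit_ml matches an independent generic minimizer on random models", {
  set.seed(20)
  worst <- 0
  for (rep in 1:20) {
    mod <- random_factor_model(p = sample(3:5, 1), n = 60)
    fit <- fit_ml(mod$spec, mod$S, 60)
    o <- oracle_min_fml(mod$spec, mod$S, trpsupp:::sem_start(mod$spec, mod$S))
    worst <- max(worst, abs(fit$F_ml - o$value))
    expect_lt(abs(fit$F_ml - o$value), 1e-8)
  }
})

test_that("free-loading models are scale invariant; fixed-links models are not", {
  set.seed(33)
  pop <- sample_population(population_spec(n_subjects = 400, seed = 33))
  meas <- simulate_measures(pop, mode = "measure")
  mdd <- as.matrix(meas[paste0("mdd_", 1:4)])
  S_cov <- cov(mdd); S_cor <- cov2cor(S_cov)

  cong <- build_model("ss_congeneric")
  f_cov <- fit_ml(cong, S_cov, 400)
  f_cor <- fit_ml(cong, S_cor, 400)
  l1 <- f_cov$standardized$lambda[, 1]; l2 <- f_cor$standardized$lambda[, 1]
  if (sum(l1) < 0) l1 <- -l1
  if (sum(l2) < 0) l2 <- -l2
  expect_equal(l1, l2, tolerance = 1e-6)
  expect_equal(f_cov$T, f_cor$T, tolerance = 1e-5)

  fl <- build_model("ss_fixedlinks_base")
  g_cov <- fit_ml(fl, S_cov, 400)
  g_cor <- fit_ml(fl, S_cor, 400)
  # fixed loadings break scale invariance: the fits genuinely differ
  expect_gt(abs(g_cov$T - g_cor$T), 0.1)
})

test_that("degrees of freedom are accounted exactly across the registry", {
  expected <- c(g_cfa = 0, trp_cfa = 2, ss_congeneric = 2,
                ss_fixedlinks_base = 4, ss_fixedlinks = 3, trp_g = 13,
                ss_g = 13, trp_ss_corr = 19, combined = 40)
  for (nm in names(expected)) {
    spec <- build_model(nm)
    expect_equal(spec$p * (spec$p + 1) / 2 - spec$q, unname(expected[nm]),
                 info = nm)
  }
})

test_that("AIC differences equal the chi-square difference minus twice the df difference", {
  set.seed(8)
  pop <- sample_population(population_spec(n_subjects = 300, seed = 8))
  meas <- simulate_measures(pop, mode = "measure")
  S <- cov(meas[paste0("mdd_", 1:4)])
  f_base <- fit_ml(build_model("ss_fixedlinks_base"), S, 300)
  f_full <- fit_ml(build_model("ss_fixedlinks"), S, 300)
  expect_equal(f_base$aic - f_full$aic,
               (f_base$T - f_full$T) - 2 * (f_base$df - f_full$df),
               tolerance = 1e-6)
})

test_that("fit indices follow their definitions on constructed cases", {
  # T = df: zero badness, RMSEA 0 and CFI 1
  S <- diag(3); sigma <- diag(3)
  idx <- fit_indices(5, 5, 50, 3, 100, S, sigma)
  expect_equal(idx$rmsea, 0)
  expect_equal(idx$cfi, 1)
  expect_equal(idx$srmr, 0)
  # hand-computed fixture
  idx2 <- fit_indices(20, 5, 100, 10, 101, S, sigma)
  expect_equal(idx2$rmsea, sqrt(15 / (5 * 100)), tolerance = 1e-12)
  expect_equal(idx2$cfi, 1 - 15 / 90, tolerance = 1e-12)
  # SRMR from a known residual pattern
  S3 <- matrix(c(1, .4, .4, 1), 2)
  sig3 <- matrix(c(1, .3, .3, 1), 2)
  idx3 <- fit_indices(1, 1, 10, 1, 50, S3, sig3)
  expect_equal(idx3$srmr, sqrt(mean(c(0, .1, 0)^2)), tolerance = 1e-12)
})

test_that("invalid covariance input is rejected with diagnostics", {
  spec <- build_model("ss_congeneric")
  S_bad <- matrix(1, 4, 4)  # singular
  expect_error(fit_ml(spec, S_bad, 100), "positive definite")
  S_asym <- diag(4); S_asym[1, 2] <- 0.5
  expect_error(fit_ml(spec, S_asym, 100), "symmetric")
  expect_error(fit_ml(spec, diag(4), 3), "sample size")
})

test_that("identification guard rejects over-parameterized patterns", {
  lambda <- matrix(NA_real_, 2, 2)
  psi <- matrix(NA_real_, 2, 2)
  theta <- diag(NA_real_, 2)
  expect_error(cov_model_spec(lambda, psi, theta), "not identifiable")
})
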
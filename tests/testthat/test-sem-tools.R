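test_that("omega reproduces the closed-form triad solution", {
  r <- ref_bis_cor()
  triad <- triad_loadings(r)
  expect_equal(unname(triad$loadings),
               c(sqrt(.51 * .46 / .39), sqrt(.51 * .39 / .46),
                 sqrt(.46 * .39 / .51)), tolerance = 1e-12)
  fit <- fit_ml(build_model("g_cfa"), r, 273)
  lam <- fit$standardized$lambda[, 1]
  if (sum(lam) < 0) lam <- -lam
  expect_equal(unname(lam), unname(triad$loadings), tolerance = 1e-5)
  expect_equal(omega(fit), triad$omega, tolerance = 1e-5)
})

test_that("omega conventions coincide for a congeneric model and order sensibly", {
  fit <- fit_ml(build_model("trp_cfa"), ref_trp_cor(), 273)
  om_c <- omega(fit, denominator = "congeneric")
  lam <- abs(fit$standardized$lambda[, 1])
  om_formula <- sum(lam)^2 / (sum(lam)^2 + sum(1 - lam^2))
  expect_equal(om_c, om_formula, tolerance = 1e-8)
  # near-zero loadings give near-zero omega
  S0 <- diag(4) + 0.001 - diag(0.001, 4)
  fit0 <- fit_ml(build_model("trp_cfa"), S0 + diag(1e-9, 4), 273)
  expect_lt(abs(omega(fit0)), 0.05)
})

test_that("factor scores reduce to the indicator in the error-free case", {
  lambda <- matrix(1, 1, 1)
  psi <- matrix(NA_real_, 1, 1)
  theta <- matrix(0, 1, 1)
  spec <- cov_model_spec(lambda, psi, theta)
  x <- matrix(rnorm(50, sd = 2), 50, 1)
  fit <- fit_ml(spec, cov(x), 50)
  sc <- factor_scores(fit, x)
  expect_equal(as.numeric(sc), as.numeric(scale(x, scale = FALSE)),
               tolerance = 1e-6)
})

test_that("factor scores track the dominant indicator and are centered", {
  set.seed(14)
  pop <- sample_population(population_spec(n_subjects = 300, seed = 14))
  bis <- score_bis(pop$bis_subtests)
  fit <- fit_ml(build_model("g_cfa"), cov(scale(as.matrix(bis))), 300)
  sc <- factor_scores(fit, scale(as.matrix(bis)))
  expect_equal(mean(sc[, "g"]), 0, tolerance = 1e-10)
  dominant <- which.max(abs(fit$standardized$lambda[, 1]))
  expect_gt(abs(cor(sc[, "g"], as.matrix(bis)[, dominant])), 0.5)
})

test_that("Satorra-Bentler scaling is near one for normal data and above one for heavy tails", {
  set.seed(6)
  lam <- c(.8, .7, .6, .5)
  sigma0 <- lam %o% lam + diag(1 - lam^2)
  spec <- build_model("trp_cfa")
  x <- rmvn(5000, sigma0)
  fit <- fit_ml(spec, cov(x), 5000)
  sb <- sb_scale(x, fit)
  expect_equal(sb$scaling_c, 1, tolerance = 0.05)
  expect_equal(sb$T_sb, fit$T / sb$scaling_c, tolerance = 1e-10)

  # heavy-tailed margins inflate the scaling factor on average
  set.seed(61)
  cs <- replicate(60, {
    z <- rmvn(400, sigma0)
    u <- pnorm(z)
    xt <- qt(u, df = 5) / sqrt(5 / 3)  # t5 margins, unit variance
    f <- tryCatch(fit_ml(spec, cov(xt), 400), error = function(e) NULL)
    if (is.null(f) || !f$converged) NA_real_ else sb_scale(xt, f)$scaling_c
  })
  expect_gt(mean(cs, na.rm = TRUE), 1.01)
  # saturated models cannot be scaled
  fit0 <- fit_ml(build_model("g_cfa"), ref_bis_cor(), 273)
  expect_error(sb_scale(matrix(rnorm(300), 100, 3), fit0), "saturated")
})

test_that("modification indices approximate the refit improvement and find planted structure", {
  set.seed(44)
  # plant one residual covariance in a fixed-links population
  spec_gen <- population_spec(n_subjects = 5000, seed = 44)
  pop <- sample_population(spec_gen)
  mdd <- as.matrix(simulate_measures(pop, mode = "measure")[paste0("mdd_", 1:4)])
  eps <- rnorm(5000, sd = 0.04)
  mdd[, 2] <- mdd[, 2] + eps
  mdd[, 3] <- mdd[, 3] + eps  # shared disturbance: residual covariance 2-3
  S <- cov(mdd)
  fit <- fit_ml(build_model("ss_fixedlinks_base"), S, 5000)
  mi <- mod_indices(fit, candidates = "theta")
  top <- mi[1, ]
  expect_setequal(c(top$row, top$col), c("mdd_2", "mdd_3"))
  # MI approximates the actual drop in T when that parameter is freed
  refit <- fit_ml(build_model("ss_fixedlinks"), S, 5000)
  dT <- fit$T - refit$T
  expect_equal(top$mi, dT, tolerance = 0.15 * dT)
  # already-free parameters are not listed
  mi_full <- mod_indices(refit, candidates = "theta")
  expect_false(any(mi_full$row == "mdd_2" & mi_full$col == "mdd_3"))
})

test_that("latent regression recovers trivial structural cases", {
  set.seed(28)
  # zero latent covariance: beta and R2 vanish
  lam <- c(.8, .7, .6, .5)
  p_tim <- lam %o% lam + diag(1 - lam^2)
  b <- c(.776, .658, .593)
  p_bis <- b %o% b + diag(1 - b^2)
  sigma0 <- rbind(cbind(p_tim, matrix(0, 4, 3)),
                  cbind(matrix(0, 3, 4), p_bis))
  fit <- latent_regression(build_model("trp_g"), sigma0, 273)
  expect_equal(fit$standardized$beta["g", "trp"], 0, tolerance = 1e-5)
  expect_equal(unname(fit$r2["g"]), 0, tolerance = 1e-5)
  # single standardized predictor: R2 = beta^2
  x <- rmvn(500, default_latent_corr())
  pop <- sample_population(population_spec(n_subjects = 500, seed = 28))
  meas <- simulate_measures(pop, mode = "measure")
  fd <- scale(meas[c("dl_empty", "dl_filled", "tg_inverted", "rp_threshold",
                     "bis_capacity", "bis_speed", "bis_memory")])
  fit2 <- latent_regression(build_model("trp_g"), cov(fd), 500)
  expect_equal(unname(fit2$r2["g"]),
               fit2$standardized$beta["g", "trp"]^2, tolerance = 1e-6)
  # a model without free structural paths is rejected
  expect_error(latent_regression(build_model("trp_cfa"), ref_trp_cor(), 273),
               "structural")
})
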
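test_that("descriptive moments match the direct formula oracle", {
  set.seed(12)
  x <- rlnorm(20, 3, 0.6)
  d <- describe(x)
  o <- oracle_describe(x)
  expect_equal(d$mean, o$mean, tolerance = 1e-12)
  expect_equal(d$sd, o$sd, tolerance = 1e-12)
  expect_equal(d$skewness, o$skewness, tolerance = 1e-10)
  expect_equal(d$kurtosis, o$kurtosis, tolerance = 1e-10)
  skip_if_not_installed("e1071")
  expect_equal(d$skewness, e1071::skewness(x, type = 2), tolerance = 1e-10)
  expect_equal(d$kurtosis, e1071::kurtosis(x, type = 2), tolerance = 1e-10)
})

test_that("descriptives handle symmetry and degenerate input", {
  expect_equal(describe(c(-1, 0, 1))$skewness, 0)
  d <- describe(rep(4, 10))
  expect_equal(d$sd, 0)
  expect_true(is.na(d$skewness) && is.na(d$kurtosis))
  expect_error(describe(3), "at least 2")
})

test_that("pearson matches cor.test and flags degenerate input", {
  set.seed(5)
  x <- rnorm(40); y <- 0.4 * x + rnorm(40)
  res <- pearson(x, y)
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)
  expect_true(res$ci_low <= res$r && res$r <= res$ci_high)
  ident <- pearson(x, x)
  expect_equal(ident$r, 1)
  expect_true(ident$flagged)
  expect_error(pearson(x, rep(2, 40)), "zero variance")
  expect_error(pearson(x[1:3], y[1:3]), "at least 4")
})

test_that("Fisher-z intervals have close to nominal coverage", {
  set.seed(7)
  rho <- 0.3
  sigma <- matrix(c(1, rho, rho, 1), 2)
  hits <- replicate(4000, {
    xy <- rmvn(47, sigma)
    ci <- fisher_ci(cor(xy[, 1], xy[, 2]), 47)
    ci[1] <= rho && rho <= ci[2]
  })
  expect_equal(mean(hits), 0.95, tolerance = 0.012)
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(8:15, 1); k <- sample(3:5, 1)
    y <- matrix(rnorm(n * k), n, k) + rnorm(n)  # subject effects
    res <- rm_anova(y)
    o <- oracle_rm_anova(y)
    expect_equal(res$F, o$F, tolerance = 1e-10)
    expect_equal(unname(res$ss["condition"]), o$ss_cond, tolerance = 1e-10)
    expect_equal(unname(res$ss["error"]), o$ss_err, tolerance = 1e-10)
    expect_equal(res$epsilon_gg, min(max(o$epsilon_gg, 1 / (k - 1)), 1),
                 tolerance = 1e-10)
  }
})

test_that("ANOVA agrees with aov and handles its edge cases", {
  set.seed(17)
  n <- 10; k <- 4
  y <- matrix(rnorm(n * k, sd = 0.5), n, k) +
    matrix(rep(c(0, 0.3, 0.8, 1), each = n), n, k)
  res <- rm_anova(y)
  long <- data.frame(y = as.vector(y),
                     subj = factor(rep(seq_len(n), k)),
                     cond = factor(rep(seq_len(k), each = n)))
  fit <- summary(aov(y ~ cond + Error(subj / cond), data = long))
  F_aov <- fit[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(res$F, F_aov, tolerance = 1e-8)
  # two conditions are always spherical
  expect_equal(rm_anova(y[, 1:2])$epsilon_gg, 1)
  # exactly equal condition means give F = 0
  y0 <- scale(matrix(rnorm(n * k), n, k), center = TRUE, scale = FALSE)
  expect_equal(rm_anova(y0)$F, 0, tolerance = 1e-20)
  expect_error(rm_anova(y[1:3, ]), "more subjects")
  # pairwise tests are Bonferroni-scaled with m = k(k-1)/2
  expect_equal(nrow(res$pairwise), 6)
  expect_equal(res$pairwise$p_bonferroni,
               pmin(res$pairwise$p_raw * 6, 1))
})

test_that("upper-half subsampling restricts range as expected", {
  set.seed(9)
  n <- 200
  x <- rnorm(n); y <- rnorm(n)
  d <- data.frame(g = rnorm(n), x = x, y = y)
  res <- split_half_subsample_corr(d, "g", "x", "y")
  expect_true(res$ci_low <= 0 && 0 <= res$ci_high)
  expect_equal(attr(res, "n_upper"), 100)
  d2 <- data.frame(g = x, x = x, y = x)
  expect_equal(split_half_subsample_corr(d2, "g", "x", "y")$r, 1)
  # range restriction shrinks a true correlation on average
  set.seed(10)
  shrunk <- replicate(300, {
    xy <- rmvn(120, matrix(c(1, .5, .5, 1), 2))
    dd <- data.frame(g = xy[, 1], x = xy[, 1], y = xy[, 2])
    c(full = cor(xy[, 1], xy[, 2]),
      half = split_half_subsample_corr(dd, "g", "x", "y")$r)
  })
  expect_lt(mean(abs(shrunk["half", ])), mean(abs(shrunk["full", ])))
})
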
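#' Descriptive statistics with adjusted higher moments
#'
#' Mean, sample SD (n-1 denominator), range, and the bias-adjusted sample
#' skewness and excess kurtosis (the SPSS/SAS convention: a normal
#' distribution has skewness 0 and kurtosis 0). A constant vector is
#' returned with SD 0 and flagged skewness/kurtosis (`NA`).
#'
#' @param x numeric vector, `n >= 2`.
#' @return data frame with `n, mean, sd, min, max, skewness, kurtosis`.
#' @export
describe <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("describe() needs at least 2 finite values")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    sk <- ku <- NA_real_
  } else {
    m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
    g1 <- m3 / m2^1.5
    g2 <- m4 / m2^2 - 3
    sk <- g1 * sqrt(n * (n - 1)) / (n - 2)
    ku <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  data.frame(n = n, mean = m, sd = s, min = min(x), max = max(x),
             skewness = sk, kurtosis = ku)
}

#' Fisher-z confidence interval for a correlation
#'
#' @param r correlation coefficient.
#' @param n sample size (> 3).
#' @param level confidence level.
#' @return `c(low, high)` on the correlation scale.
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  stopifnot(n > 3, abs(r) <= 1)
  if (abs(r) == 1) return(c(r, r))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(z + c(-1, 1) * q * se)
}

#' Pearson correlation with test and Fisher-z interval
#'
#' Computed from the product-moment formula; the two-sided p value uses
#' the t transform `r * sqrt((n-2)/(1-r^2))` and the confidence interval
#' the Fisher z transform with standard error `1/sqrt(n-3)`.
#'
#' @param x,y numeric vectors of equal length, `n >= 4`.
#' @param level confidence level for the interval.
#' @return one-row data frame `r, n, p_value, ci_low, ci_high, flagged`
#'   (flagged when `|r| = 1` and the interval is degenerate).
#' @export
pearson <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("pearson() needs at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- min(max(r, -1), 1)
  degenerate <- abs(r) >= 1 - 1e-12
  p <- if (degenerate) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  ci <- fisher_ci(r, n, level)
  data.frame(r = r, n = n, p_value = p, ci_low = ci[1], ci_high = ci[2],
             flagged = degenerate)
}

#' Pairwise Pearson correlation matrix
#'
#' @param data data frame of numeric columns.
#' @return list with matrices `r`, `p`, and the common `n`.
#' @export
corr_matrix <- function(data) {
  x <- as.matrix(data)
  p <- ncol(x)
  r <- diag(p); pv <- matrix(0, p, p)
  dimnames(r) <- dimnames(pv) <- list(colnames(x), colnames(x))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    res <- pearson(x[, i], x[, j])
    r[i, j] <- r[j, i] <- res$r
    pv[i, j] <- pv[j, i] <- res$p_value
  }
  list(r = r, p = pv, n = nrow(x))
}

#' One-way repeated-measures ANOVA with sphericity diagnostics
#'
#' Within-subject F test for `k` conditions measured on every subject,
#' with Mauchly's sphericity test (chi-square approximation),
#' Greenhouse-Geisser epsilon computed from the eigenvalues of the
#' contrast-projected condition covariance, epsilon-corrected degrees of
#' freedom and p value, three eta-squared variants, and
#' Bonferroni-adjusted pairwise paired t tests (`m = k(k-1)/2`).
#'
#' @param y numeric matrix, subjects x conditions (complete cases).
#' @return list of class `rm_anova` with the test, sphericity, effect
#'   size, and pairwise components.
#' @export
rm_anova <- function(y) {
  y <- as.matrix(y)
  n <- nrow(y); k <- ncol(y)
  stopifnot(k >= 2)
  if (n <= k) stop("need more subjects than conditions")
  if (anyNA(y)) stop("complete cases required")

  grand <- mean(y)
  cond_means <- colMeans(y)
  subj_means <- rowMeans(y)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  F <- (ss_cond / df1) / (ss_err / df2)

  # orthonormal contrasts; epsilon and Mauchly from C' S C
  C <- qr.Q(qr(cbind(1, diag(k))))[, -1, drop = FALSE]
  S <- stats::cov(y)
  M <- t(C) %*% S %*% C
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  eps_gg <- if (k == 2) 1 else sum(ev)^2 / ((k - 1) * sum(ev^2))
  eps_gg <- min(max(eps_gg, 1 / (k - 1)), 1)

  W <- prod(ev) / (mean(ev))^(k - 1)
  d <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * (n - 1))
  chi <- -(n - 1) * d * log(max(W, .Machine$double.xmin))
  df_m <- k * (k - 1) / 2 - 1
  mauchly_p <- if (df_m > 0) stats::pchisq(chi, df_m, lower.tail = FALSE) else NA_real_

  p_unc <- stats::pf(F, df1, df2, lower.tail = FALSE)
  p_gg <- stats::pf(F, eps_gg * df1, eps_gg * df2, lower.tail = FALSE)

  m <- k * (k - 1) / 2
  pairs <- utils::combn(k, 2)
  pw <- data.frame(i = pairs[1, ], j = pairs[2, ])
  pw$t <- pw$p_raw <- NA_real_
  for (r in seq_len(m)) {
    d_ <- y[, pw$i[r]] - y[, pw$j[r]]
    tt <- mean(d_) / (stats::sd(d_) / sqrt(n))
    pw$t[r] <- tt
    pw$p_raw[r] <- 2 * stats::pt(-abs(tt), df = n - 1)
  }
  pw$p_bonferroni <- pmin(pw$p_raw * m, 1)

  structure(list(F = F, df1 = df1, df2 = df2, p_uncorrected = p_unc,
                 epsilon_gg = eps_gg, df1_gg = eps_gg * df1,
                 df2_gg = eps_gg * df2, p_gg = p_gg,
                 mauchly_W = W, mauchly_chisq = chi, mauchly_df = df_m,
                 mauchly_p = mauchly_p,
                 eta_sq = ss_cond / ss_tot,
                 eta_sq_partial = ss_cond / (ss_cond + ss_err),
                 eta_sq_generalized = ss_cond / (ss_cond + ss_subj + ss_err),
                 ss = c(condition = ss_cond, subject = ss_subj,
                        error = ss_err, total = ss_tot),
                 pairwise = pw, n = n, k = k),
            class = "rm_anova")
}

#' Correlation within the upper half of a sample
#'
#' Splits the sample at the median of `split_var` and computes the
#' Pearson correlation of two variables within the upper half (values
#' `>= median`; median ties are noted in the result).
#'
#' @param data data frame.
#' @param split_var name of the ordering variable.
#' @param var1,var2 names of the variables to correlate.
#' @return [pearson()] result with attributes `n_upper` and `ties_at_median`.
#' @export
split_half_subsample_corr <- function(data, split_var, var1, var2) {
  s <- data[[split_var]]
  med <- stats::median(s)
  upper <- s >= med
  res <- pearson(data[[var1]][upper], data[[var2]][upper])
  attr(res, "n_upper") <- sum(upper)
  attr(res, "ties_at_median") <- sum(s == med)
  res
}
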
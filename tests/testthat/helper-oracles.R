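# Independent oracles used to cross-check the package's own
# implementations. Each one recomputes the target quantity by a
# different route (direct moment formulas, explicit sums of squares, or
# a generic derivative-free optimizer).

# descriptive moments, written out directly from the adjusted-moment
# formulas (cross-checked against e1071 where available)
oracle_describe <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  dev <- x - m
  m2 <- sum(dev^2) / n
  m3 <- sum(dev^3) / n
  m4 <- sum(dev^4) / n
  g1 <- m3 / m2^(3 / 2)
  g2 <- m4 / m2^2 - 3
  list(mean = m,
       sd = sqrt(sum(dev^2) / (n - 1)),
       skewness = g1 * sqrt(n * (n - 1)) / (n - 2),
       kurtosis = ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)))
}

# one-way repeated-measures ANOVA by explicit sums of squares, with the
# Greenhouse-Geisser epsilon from the double-centered covariance matrix
# (a different route than the package's contrast-eigenvalue form)
oracle_rm_anova <- function(y) {
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  ss_cond <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(y[, j]) - grand)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(y[i, ]) - grand)^2
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  S <- stats::cov(y)
  rowm <- rowMeans(S); colm <- colMeans(S); gm <- mean(S)
  Cb <- S - outer(rowm, rep(1, k)) - outer(rep(1, k), colm) + gm
  eps <- sum(diag(Cb))^2 / ((k - 1) * sum(Cb^2))
  list(F = F, ss_cond = ss_cond, ss_subj = ss_subj, ss_err = ss_err,
       epsilon_gg = eps)
}

# the ML discrepancy built independently from the spec's pattern tables
oracle_fml <- function(spec, par, S) {
  L <- spec$lambda; B <- spec$beta; P <- spec$psi; Th <- spec$theta
  pt <- spec$par_table
  for (k in seq_len(nrow(pt))) {
    v <- par[k]; i <- pt$i[k]; j <- pt$j[k]
    if (pt$mat[k] == "lambda") L[i, j] <- v
    if (pt$mat[k] == "beta") B[i, j] <- v
    if (pt$mat[k] == "psi") { P[i, j] <- v; P[j, i] <- v }
    if (pt$mat[k] == "theta") { Th[i, j] <- v; Th[j, i] <- v }
  }
  E <- solve(diag(ncol(L)) - B)
  sig <- L %*% E %*% P %*% t(E) %*% t(L) + Th
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(1e10)
  as.numeric(determinant(sig, logarithm = TRUE)$modulus -
               determinant(S, logarithm = TRUE)$modulus +
               sum(diag(S %*% solve(sig))) - nrow(S))
}

# generic minimization of the same objective: Nelder-Mead, then a
# numeric-gradient BFGS polish, then Nelder-Mead again
oracle_min_fml <- function(spec, S, start) {
  fn <- function(p) oracle_fml(spec, p, S)
  o <- stats::optim(start, fn, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  o <- stats::optim(o$par, fn, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14))
  o <- stats::optim(o$par, fn, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  o
}

# random well-conditioned one-factor model and a sample covariance from it
random_factor_model <- function(p = 4, n = 80) {
  lam_true <- stats::runif(p, 0.5, 0.9)
  th_true <- stats::runif(p, 0.3, 0.8)
  sigma0 <- lam_true %o% lam_true + diag(th_true)
  x <- rmvn(n, sigma0)
  lambda <- matrix(NA_real_, p, 1)
  psi <- matrix(1, 1, 1)
  theta <- diag(NA_real_, p)
  list(spec = cov_model_spec(lambda, psi, theta), S = stats::cov(x),
       sigma0 = sigma0, lam_true = lam_true, th_true = th_true)
}
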
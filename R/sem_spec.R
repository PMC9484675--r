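#' Specify a structured covariance model
#'
#' A model for a p x p covariance matrix with m latent variables:
#' \deqn{\Sigma = \Lambda (I-B)^{-1} \Phi (I-B)^{-T} \Lambda' + \Theta}
#' where `lambda` (p x m) holds factor loadings, `beta` (m x m) holds
#' directed latent regressions (zero diagonal), `psi` (m x m, symmetric)
#' the covariances of exogenous latents and latent disturbances, and
#' `theta` (p x p, symmetric) the residual covariances. In every pattern
#' matrix a numeric entry is a fixed value and `NA` marks a free
#' parameter; fixed entries are immutable during fitting. Symmetric
#' matrices are read from their lower triangle.
#'
#' Free parameters may carry box constraints via `lower`/`upper`
#' (matrices of the same shape; `NA` means unbounded), e.g. to restrict
#' a residual variance to positive values.
#'
#' @param lambda p x m loading pattern (numeric with `NA` = free).
#' @param psi m x m symmetric factor/disturbance covariance pattern.
#' @param theta p x p symmetric residual covariance pattern.
#' @param beta optional m x m latent regression pattern (default all
#'   zero, i.e. no structural part).
#' @param obs_names,lat_names variable names (default from dimnames).
#' @param lower,upper optional named lists of bound matrices (elements
#'   `lambda`, `beta`, `psi`, `theta`).
#' @param start optional named list of start-value matrices for free
#'   cells.
#' @return an object of class `cov_model_spec`.
#' @export
cov_model_spec <- function(lambda, psi, theta, beta = NULL,
                           obs_names = NULL, lat_names = NULL,
                           lower = NULL, upper = NULL, start = NULL) {
  lambda <- as.matrix(lambda)
  p <- nrow(lambda); m <- ncol(lambda)
  psi <- as.matrix(psi); theta <- as.matrix(theta)
  stopifnot(nrow(psi) == m, ncol(psi) == m,
            nrow(theta) == p, ncol(theta) == p)
  if (is.null(beta)) beta <- matrix(0, m, m)
  beta <- as.matrix(beta)
  stopifnot(nrow(beta) == m, ncol(beta) == m)
  if (any(is.na(diag(beta))) || any(diag(beta) != 0))
    stop("beta must have a fixed zero diagonal")
  sym_check <- function(x, nm) {
    lo <- x[lower.tri(x)]; up <- t(x)[lower.tri(x)]
    ok <- (is.na(lo) & is.na(up)) | (!is.na(lo) & !is.na(up) & lo == up)
    if (!all(ok)) stop(nm, " pattern must be symmetric (including NA positions)")
  }
  sym_check(psi, "psi"); sym_check(theta, "theta")

  obs_names <- obs_names %||% rownames(lambda) %||% paste0("x", seq_len(p))
  lat_names <- lat_names %||% colnames(lambda) %||% paste0("f", seq_len(m))
  dimnames(lambda) <- list(obs_names, lat_names)
  dimnames(psi) <- list(lat_names, lat_names)
  dimnames(theta) <- list(obs_names, obs_names)
  dimnames(beta) <- list(lat_names, lat_names)

  cell_name <- function(mat, i, j, rn, cn) sprintf("%s[%s,%s]", mat, rn[i], cn[j])
  get_bound <- function(bl, mat, i, j, default) {
    b <- bl[[mat]]
    if (is.null(b) || is.na(b[i, j])) default else b[i, j]
  }
  pars <- list()
  add <- function(mat, i, j, rn, cn) {
    pars[[length(pars) + 1]] <<- data.frame(
      mat = mat, i = i, j = j,
      label = cell_name(mat, i, j, rn, cn),
      lower = get_bound(lower, mat, i, j, -Inf),
      upper = get_bound(upper, mat, i, j, Inf),
      start = { s <- start[[mat]]; if (is.null(s)) NA_real_ else s[i, j] })
  }
  for (j in seq_len(m)) for (i in seq_len(p))
    if (is.na(lambda[i, j])) add("lambda", i, j, obs_names, lat_names)
  for (j in seq_len(m)) for (i in seq_len(m))
    if (is.na(beta[i, j])) add("beta", i, j, lat_names, lat_names)
  for (j in seq_len(m)) for (i in j:m)
    if (is.na(psi[i, j])) add("psi", i, j, lat_names, lat_names)
  for (j in seq_len(p)) for (i in j:p)
    if (is.na(theta[i, j])) add("theta", i, j, obs_names, obs_names)
  par_table <- if (length(pars)) do.call(rbind, pars) else
    data.frame(mat = character(), i = integer(), j = integer(),
               label = character(), lower = numeric(), upper = numeric(),
               start = numeric())

  q <- nrow(par_table)
  if (q > p * (p + 1) / 2)
    stop(sprintf("model not identifiable: %d free parameters exceed %d unique covariance elements",
                 q, p * (p + 1) / 2))

  structure(list(p = p, m = m, lambda = lambda, beta = beta, psi = psi,
                 theta = theta, obs_names = obs_names,
                 lat_names = lat_names, par_table = par_table, q = q),
            class = "cov_model_spec")
}

#' @export
print.cov_model_spec <- function(x, ...) {
  cat(sprintf("Structured covariance model: %d observed, %d latent, %d free parameters (df = %d)\n",
              x$p, x$m, x$q, x$p * (x$p + 1) / 2 - x$q))
  invisible(x)
}

# fill the pattern matrices with a free-parameter vector
sem_matrices <- function(spec, par) {
  L <- spec$lambda; B <- spec$beta; P <- spec$psi; Th <- spec$theta
  pt <- spec$par_table
  for (k in seq_len(nrow(pt))) {
    v <- par[k]
    switch(pt$mat[k],
           lambda = { L[pt$i[k], pt$j[k]] <- v },
           beta   = { B[pt$i[k], pt$j[k]] <- v },
           psi    = { P[pt$i[k], pt$j[k]] <- v; P[pt$j[k], pt$i[k]] <- v },
           theta  = { Th[pt$i[k], pt$j[k]] <- v; Th[pt$j[k], pt$i[k]] <- v })
  }
  list(lambda = L, beta = B, psi = P, theta = Th)
}

# model-implied covariance matrix from a free-parameter vector
implied_sigma <- function(spec, par) {
  mats <- sem_matrices(spec, par)
  E <- solve(diag(spec$m) - mats$beta)
  A <- mats$lambda %*% E
  sig <- A %*% mats$psi %*% t(A) + mats$theta
  (sig + t(sig)) / 2
}

# typical magnitude of each free parameter, used to condition the
# optimizer (parscale) and the gradient-norm convergence check
sem_parscale <- function(spec, S) {
  pt <- spec$par_table
  sdS <- sqrt(diag(S))
  psi_scale <- vapply(seq_len(spec$m), function(k) {
    v <- spec$psi[k, k]
    if (!is.na(v) && v > 0) return(v)
    lam <- spec$lambda[, k]
    fx <- lam[!is.na(lam) & lam != 0]
    if (length(fx)) mean(diag(S)) / mean(fx^2) else 1
  }, numeric(1))
  ps <- numeric(nrow(pt))
  for (k in seq_len(nrow(pt))) {
    i <- pt$i[k]; j <- pt$j[k]
    ps[k] <- switch(pt$mat[k],
                    lambda = sdS[i] / sqrt(psi_scale[j]),
                    beta = 1,
                    psi = sqrt(psi_scale[i] * psi_scale[j]),
                    theta = sdS[i] * sdS[j])
  }
  pmax(ps, 1e-8)
}

# default start values, scale-aware in S
sem_start <- function(spec, S) {
  pt <- spec$par_table
  sdS <- sqrt(diag(S))
  start <- numeric(nrow(pt))
  mean_diag <- mean(diag(S))
  for (k in seq_len(nrow(pt))) {
    if (!is.na(pt$start[k])) { start[k] <- pt$start[k]; next }
    start[k] <- switch(pt$mat[k],
      lambda = 0.7 * sdS[pt$i[k]],
      beta = 0,
      psi = if (pt$i[k] == pt$j[k]) {
        lam <- spec$lambda[, pt$i[k]]
        fx <- lam[!is.na(lam) & lam != 0]
        if (length(fx)) 0.5 * mean_diag / mean(fx^2) else 0.5
      } else 0,
      theta = if (pt$i[k] == pt$j[k]) 0.5 * S[pt$i[k], pt$i[k]] else 0)
    start[k] <- min(max(start[k], pt$lower[k] + 1e-8), pt$upper[k] - 1e-8)
  }
  start
}
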
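#' Satorra-Bentler mean-scaled test statistic
#'
#' Computes the mean-scaling factor `c = tr(U Gamma) / df` from the raw
#' data's fourth-moment estimate of the asymptotic covariance of the
#' unique sample-covariance elements (`Gamma`), with `U` the standard
#' normal-theory residual weight matrix evaluated at the fitted model.
#' For multivariate normal data `c` tends to 1; heavy tails push it
#' above 1. `T_sb = T / c`.
#'
#' @param x raw data matrix (subjects x variables, same order as the
#'   fitted `S`).
#' @param fit a converged [fit_ml()] result with `df >= 1`.
#' @return list with `scaling_c`, `T_sb`, `p_value_sb`.
#' @export
sb_scale <- function(x, fit) {
  stopifnot(inherits(fit, "sem_fit"))
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  stopifnot(p == fit$spec$p)
  if (fit$df < 1) stop("scaling undefined for a saturated model")
  if (n < 5 * p) warning("sample may be too small for stable fourth moments")

  xc <- sweep(x, 2, colMeans(x))
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  d <- xc[, idx[, 1], drop = FALSE] * xc[, idx[, 2], drop = FALSE]
  dc <- sweep(d, 2, colMeans(d))
  Gamma <- crossprod(dc) / n

  D <- duplication_matrix(p)
  siginv <- solve(fit$sigma_hat)
  V <- 0.5 * t(D) %*% (siginv %x% siginv) %*% D

  # Delta = d vech(Sigma) / d theta', by central differences
  q <- fit$spec$q
  Delta <- matrix(0, p * (p + 1) / 2, q)
  h <- 1e-6
  for (k in seq_len(q)) {
    pk <- fit$theta_hat
    pk[k] <- pk[k] + h
    sp <- vech(implied_sigma(fit$spec, pk))
    pk[k] <- pk[k] - 2 * h
    sm <- vech(implied_sigma(fit$spec, pk))
    Delta[, k] <- (sp - sm) / (2 * h)
  }
  U <- if (q > 0) {
    VD <- V %*% Delta
    V - VD %*% solve(t(Delta) %*% VD, t(VD))
  } else V
  c_hat <- sum(diag(U %*% Gamma)) / fit$df
  T_sb <- fit$T / c_hat
  list(scaling_c = c_hat, T_sb = T_sb,
       p_value_sb = stats::pchisq(T_sb, fit$df, lower.tail = FALSE))
}

#' McDonald's omega composite reliability
#'
#' For a one-factor (congeneric) model the standardized form
#' `omega = (sum lambda*)^2 / (1' Sigma* 1)` is used, which reduces to
#' `(sum lambda)^2 / ((sum lambda)^2 + sum theta)` with uncorrelated
#' residuals. For multi-factor models, `denominator = "total"` (default)
#' reports the share of unit-weight composite variance due to factor f,
#' `(1'Lambda_f)^2 phi_f / (1' Sigma_hat 1)`; `"factor_specific"`
#' replaces the denominator with `(1'Lambda_f)^2 phi_f + 1' Theta 1`,
#' i.e. reliability relative to that factor plus error only.
#'
#' @param fit a converged [fit_ml()] result.
#' @param factor index or name of the factor.
#' @param denominator `"auto"`, `"congeneric"`, `"total"`, or
#'   `"factor_specific"`.
#' @return omega in \[0, 1\].
#' @export
omega <- function(fit, factor = 1,
                  denominator = c("auto", "congeneric", "total",
                                  "factor_specific")) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) stop("omega requires a converged fit")
  denominator <- match.arg(denominator)
  if (is.character(factor)) factor <- match(factor, fit$spec$lat_names)
  if (denominator == "auto")
    denominator <- if (fit$spec$m == 1) "congeneric" else "total"
  if (denominator == "congeneric") {
    lam <- fit$standardized$lambda[, factor]
    sig_std <- fit$sigma_hat / (sqrt(diag(fit$sigma_hat)) %o%
                                  sqrt(diag(fit$sigma_hat)))
    num <- sum(lam)^2 * fit$standardized$psi[factor, factor]
    return(num / sum(sig_std))
  }
  lam <- fit$matrices$lambda[, factor]
  phi <- fit$latent_cov[factor, factor]
  num <- sum(lam)^2 * phi
  den <- switch(denominator,
                total = sum(fit$sigma_hat),
                factor_specific = num + sum(fit$matrices$theta))
  num / den
}

#' Regression-method factor scores
#'
#' Scores each subject on every latent variable by the regression
#' estimator `cov(eta, x) Sigma^-1 (x - xbar)`, where
#' `cov(eta, x) = (I-B)^-1 Psi (I-B)^-T Lambda'`.
#'
#' @param fit a converged [fit_ml()] result.
#' @param x raw data matrix (subjects x variables, same variables and
#'   scale as the fitted `S`).
#' @return an n x m matrix of factor scores.
#' @export
factor_scores <- function(fit, x) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) stop("factor scores require a converged fit")
  x <- as.matrix(x)
  stopifnot(ncol(x) == fit$spec$p)
  siginv <- tryCatch(solve(fit$sigma_hat),
                     error = function(e) stop("implied covariance is singular"))
  xc <- sweep(x, 2, colMeans(x))
  sc <- xc %*% siginv %*% fit$matrices$lambda %*% fit$latent_cov
  colnames(sc) <- fit$spec$lat_names
  sc
}

#' Modification indices for fixed parameters
#'
#' Univariate score-test statistics: for each fixed cell of the loading,
#' latent-covariance and residual-covariance matrices, the approximate
#' drop in the test statistic T that freeing that single parameter would
#' produce, `MI = s^2 / (2 h)`, where `s` is the gradient of T in the
#' fixed direction at the solution and `h` the Schur complement of that
#' direction in the Hessian of T (finite differences of the analytic
#' gradient).
#'
#' @param fit a converged [fit_ml()] result with `df >= 1`.
#' @param candidates which matrices to scan (default residual and latent
#'   covariances and loadings).
#' @return data frame `matrix, row, col, mi`, sorted by decreasing `mi`.
#' @export
mod_indices <- function(fit, candidates = c("theta", "psi", "lambda")) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) stop("modification indices require a converged fit")
  if (fit$df < 1) stop("saturated model: nothing to free")
  spec <- fit$spec; S <- fit$S
  mult <- if (fit$multiplier == "n-1") fit$n - 1 else fit$n
  pt <- spec$par_table
  q <- spec$q

  # candidate fixed cells (lower triangle for symmetric matrices)
  cand <- list()
  if ("theta" %in% candidates)
    for (j in seq_len(spec$p)) for (i in j:spec$p)
      if (!is.na(spec$theta[i, j])) cand[[length(cand) + 1]] <- c("theta", i, j)
  if ("psi" %in% candidates)
    for (j in seq_len(spec$m)) for (i in j:spec$m)
      if (!is.na(spec$psi[i, j])) cand[[length(cand) + 1]] <- c("psi", i, j)
  if ("lambda" %in% candidates)
    for (j in seq_len(spec$m)) for (i in seq_len(spec$p))
      if (!is.na(spec$lambda[i, j])) cand[[length(cand) + 1]] <- c("lambda", i, j)
  if (!length(cand)) return(data.frame())

  # extended spec: same pattern but with one extra free cell
  free_cell <- function(mat, i, j) {
    L <- spec$lambda; P <- spec$psi; Th <- spec$theta; B <- spec$beta
    if (mat == "lambda") L[i, j] <- NA
    if (mat == "psi") { P[i, j] <- NA; P[j, i] <- NA }
    if (mat == "theta") { Th[i, j] <- NA; Th[j, i] <- NA }
    cov_model_spec(L, P, Th, B, spec$obs_names, spec$lat_names)
  }

  out <- data.frame()
  for (cc in cand) {
    mat <- cc[1]; i <- as.integer(cc[2]); j <- as.integer(cc[3])
    spec_ext <- free_cell(mat, i, j)
    # map the fitted free parameters + the candidate into the extended order
    pt_ext <- spec_ext$par_table
    par_ext <- numeric(nrow(pt_ext))
    cand_pos <- NA_integer_
    fixed_val <- switch(mat, lambda = spec$lambda[i, j],
                        psi = spec$psi[i, j], theta = spec$theta[i, j])
    for (k in seq_len(nrow(pt_ext))) {
      hit <- which(pt$mat == pt_ext$mat[k] & pt$i == pt_ext$i[k] &
                     pt$j == pt_ext$j[k])
      if (length(hit)) par_ext[k] <- fit$theta_hat[hit]
      else { par_ext[k] <- fixed_val; cand_pos <- k }
    }
    g_ext <- function(par) mult * sem_fml_grad(spec_ext, par, S)
    # Hessian of T by central differences of the analytic gradient
    qe <- length(par_ext)
    H <- matrix(0, qe, qe)
    h <- 1e-5
    for (k in seq_len(qe)) {
      pk <- par_ext; pk[k] <- pk[k] + h; gp <- g_ext(pk)
      pk[k] <- pk[k] - 2 * h; gm <- g_ext(pk)
      H[, k] <- (gp - gm) / (2 * h)
    }
    H <- (H + t(H)) / 2
    s <- g_ext(par_ext)[cand_pos]
    oth <- setdiff(seq_len(qe), cand_pos)
    v <- if (length(oth)) {
      Hoo <- H[oth, oth, drop = FALSE]
      sol <- tryCatch(solve(Hoo, H[oth, cand_pos]), error = function(e) NULL)
      if (is.null(sol)) NA_real_ else H[cand_pos, cand_pos] - sum(H[cand_pos, oth] * sol)
    } else H[cand_pos, cand_pos]
    mi <- if (is.na(v) || v <= 0) NA_real_ else s^2 / (2 * v)
    out <- rbind(out, data.frame(
      matrix = mat, row = spec$obs_names[i] %||% i, col = j, mi = mi,
      stringsAsFactors = FALSE))
    # use latent names for psi rows/cols, observed for theta/lambda rows
    out$row[nrow(out)] <- if (mat == "psi") spec$lat_names[i] else spec$obs_names[i]
    out$col[nrow(out)] <- if (mat == "theta") spec$obs_names[j] else spec$lat_names[j]
  }
  out[order(-out$mi), ]
}

#' Latent regression fit
#'
#' Fits a model whose structural part regresses endogenous latent
#' variables on others (free cells in the `beta` pattern), and reports
#' the standardized structural coefficients and the R-squared of each
#' endogenous latent alongside the full fit.
#'
#' @param spec a [cov_model_spec()] with at least one free `beta` cell.
#' @param S sample covariance matrix.
#' @param n sample size.
#' @param ... passed to [fit_ml()].
#' @return a [fit_ml()] result with elements `beta_std` and `r2`.
#' @export
latent_regression <- function(spec, S, n, ...) {
  if (!any(is.na(spec$beta)))
    stop("no free structural paths: declare free cells in beta")
  fit <- fit_ml(spec, S, n, ...)
  fit$beta_std <- fit$standardized$beta
  fit
}
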
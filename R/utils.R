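#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw from a multivariate normal via Cholesky factorisation
#'
#' Uses the current R random number stream, so results are reproducible
#' under `set.seed()`.
#'
#' @param n number of draws.
#' @param sigma covariance matrix (symmetric positive semi-definite).
#' @param mean mean vector (recycled to `ncol(sigma)`).
#' @return an `n x ncol(sigma)` matrix.
#' @export
rmvn <- function(n, sigma, mean = 0) {
  p <- ncol(sigma)
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop("covariance matrix is not positive semi-definite")
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% rt, 2, rep_len(mean, p), `+`)
}

#' Check a correlation matrix for validity
#' @param r matrix to check.
#' @param tol eigenvalue tolerance relative to the largest eigenvalue.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_corr_matrix <- function(r, tol = 1e-8) {
  if (!is.matrix(r) || nrow(r) != ncol(r))
    stop("latent correlation matrix must be square")
  if (max(abs(r - t(r))) > 1e-10)
    stop("latent correlation matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-10)
    stop("latent correlation matrix must have unit diagonal")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(ev))
    stop(sprintf("latent correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
                 min(ev)))
  invisible(TRUE)
}

# half-vectorisation of a symmetric matrix (columnwise lower triangle)
vech <- function(m) m[lower.tri(m, diag = TRUE)]

# duplication matrix D_p: vec(S) = D %*% vech(S) for symmetric S
duplication_matrix <- function(p) {
  pos <- matrix(0L, p, p)
  pos[lower.tri(pos, diag = TRUE)] <- seq_len(p * (p + 1) / 2)
  pos[upper.tri(pos)] <- t(pos)[upper.tri(pos)]
  D <- matrix(0, p * p, p * (p + 1) / 2)
  D[cbind(seq_len(p * p), as.vector(pos))] <- 1
  D
}

# Run code with a temporary RNG state; restores the caller's stream.
with_preserved_rng <- function(code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
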
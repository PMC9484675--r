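#' Reference correlation matrices from the validation sample
#'
#' Published inter-measure Pearson correlations from a validation sample
#' of 273 young adults, used as desk-scale inputs for the worked
#' analyses: the three intelligence-composite correlations (capacity,
#' speed, memory) and the four timing-task correlations (duration
#' discrimination with empty and filled intervals, temporal
#' generalization, rhythm perception).
#'
#' @return a correlation matrix with dimnames.
#' @name reference_correlations
NULL

#' @rdname reference_correlations
#' @export
ref_bis_cor <- function() {
  nm <- c("bis_capacity", "bis_speed", "bis_memory")
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.51   # capacity - speed
  r[1, 3] <- r[3, 1] <- 0.46   # capacity - memory
  r[2, 3] <- r[3, 2] <- 0.39   # speed - memory
  dimnames(r) <- list(nm, nm)
  r
}

#' @rdname reference_correlations
#' @export
ref_trp_cor <- function() {
  nm <- c("dl_empty", "dl_filled", "tg_inverted", "rp_threshold")
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 0.36   # DDE - DDF
  r[1, 3] <- r[3, 1] <- 0.25   # DDE - TG
  r[1, 4] <- r[4, 1] <- 0.26   # DDE - RP
  r[2, 3] <- r[3, 2] <- 0.34   # DDF - TG
  r[2, 4] <- r[4, 2] <- 0.17   # DDF - RP
  r[3, 4] <- r[4, 3] <- 0.16   # TG - RP
  dimnames(r) <- list(nm, nm)
  r
}

#' Closed-form one-factor solution for three indicators
#'
#' With exactly three indicators the one-factor model is exactly
#' identified and the standardized loadings have the closed triad form
#' `lambda_1 = sqrt(r12 * r13 / r23)` (and permutations).
#'
#' @param r 3x3 correlation matrix.
#' @return list with `loadings` and `omega` (congeneric composite
#'   reliability).
#' @export
triad_loadings <- function(r) {
  stopifnot(nrow(r) == 3, ncol(r) == 3)
  l <- c(sqrt(r[1, 2] * r[1, 3] / r[2, 3]),
         sqrt(r[1, 2] * r[2, 3] / r[1, 3]),
         sqrt(r[1, 3] * r[2, 3] / r[1, 2]))
  names(l) <- rownames(r)
  list(loadings = l,
       omega = sum(l)^2 / (sum(l)^2 + sum(1 - l^2)))
}
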
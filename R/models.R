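#' Model registry for the study's latent-variable analyses
#'
#' Returns the exact pattern matrices of each model in the analysis
#' chain. Variable-name conventions match [simulate_measures()]:
#' thresholds `mdd_1..mdd_4` (log10 ms, smallest to largest size),
#' timing scores `dl_empty, dl_filled, tg_inverted, rp_threshold`, and
#' composites `bis_capacity, bis_speed, bis_memory`.
#'
#' Registered models:
#' * `g_cfa`: one-factor model of the three intelligence composites
#'   (exactly identified, df = 0).
#' * `trp_cfa`: one-factor model of the four timing scores (df = 2).
#' * `ss_congeneric`: one-factor model of the four thresholds with free
#'   loadings (df = 2).
#' * `ss_fixedlinks_base`: two orthogonal fixed-links factors over the
#'   thresholds — constant loadings (1,1,1,1) and linearly increasing
#'   loadings (0,1,2,3) — with free latent variances (df = 4).
#' * `ss_fixedlinks`: the final suppression model — fixed links plus a
#'   free residual covariance between the 3.6 and 5.4 degree conditions
#'   and the first and fourth residual variances bounded above zero
#'   (df = 3).
#' * `trp_g`: g regressed on the timing factor (df = 13).
#' * `ss_g`: g regressed on both suppression components (df = 13).
#' * `trp_ss_corr`: timing factor freely correlated with both
#'   suppression components (df = 19).
#' * `combined`: g regressed simultaneously on the timing factor and
#'   both suppression components, timing correlated with both (df = 40).
#'
#' Endogenous `g` is identified by fixing its first loading to 1; latent
#' variances of free-loading exogenous factors are fixed to 1.
#'
#' @param name one of the registry names above.
#' @return a [cov_model_spec()].
#' @export
build_model <- function(name) {
  mdd <- paste0("mdd_", 1:4)
  trp <- c("dl_empty", "dl_filled", "tg_inverted", "rp_threshold")
  bis <- c("bis_capacity", "bis_speed", "bis_memory")
  w <- 0:3
  FREE <- NA_real_

  one_factor <- function(obs, fname) {
    p <- length(obs)
    lambda <- matrix(FREE, p, 1, dimnames = list(obs, fname))
    psi <- matrix(1, 1, 1, dimnames = list(fname, fname))
    theta <- diag(FREE, p); theta[upper.tri(theta) | lower.tri(theta)] <- 0
    dimnames(theta) <- list(obs, obs)
    cov_model_spec(lambda, psi, theta)
  }

  fixed_links_parts <- function(resid_23 = TRUE, bound_14 = TRUE) {
    lambda <- cbind(ssc = rep(1, 4), ssi = w)
    rownames(lambda) <- mdd
    psi <- matrix(c(FREE, 0, 0, FREE), 2, 2,
                  dimnames = list(c("ssc", "ssi"), c("ssc", "ssi")))
    theta <- diag(FREE, 4); theta[upper.tri(theta) | lower.tri(theta)] <- 0
    if (resid_23) theta[2, 3] <- theta[3, 2] <- FREE
    dimnames(theta) <- list(mdd, mdd)
    lower <- NULL
    if (bound_14) {
      lt <- matrix(NA_real_, 4, 4)
      lt[1, 1] <- 1e-6; lt[4, 4] <- 1e-6
      lower <- list(theta = lt)
    }
    list(lambda = lambda, psi = psi, theta = theta, lower = lower)
  }

  g_measurement <- function(first_fixed) {
    # loadings of the three composites on g; first fixed for identification
    l <- rep(FREE, 3)
    if (first_fixed) l[1] <- 1
    l
  }

  block_diag <- function(...) {
    mats <- list(...)
    p <- sum(vapply(mats, nrow, 1L))
    out <- matrix(0, p, p)
    nm <- character(p)
    at <- 0
    for (m_ in mats) {
      k <- nrow(m_)
      out[at + seq_len(k), at + seq_len(k)] <- m_
      nm[at + seq_len(k)] <- rownames(m_)
      at <- at + k
    }
    dimnames(out) <- list(nm, nm)
    out
  }
  diag_theta <- function(obs) {
    th <- diag(FREE, length(obs)); th[upper.tri(th) | lower.tri(th)] <- 0
    dimnames(th) <- list(obs, obs)
    th
  }

  switch(name,
    g_cfa = one_factor(bis, "g"),
    trp_cfa = one_factor(trp, "trp"),
    ss_congeneric = one_factor(mdd, "ss"),
    ss_fixedlinks_base = {
      fl <- fixed_links_parts(resid_23 = FALSE, bound_14 = FALSE)
      cov_model_spec(fl$lambda, fl$psi, fl$theta)
    },
    ss_fixedlinks = {
      fl <- fixed_links_parts()
      cov_model_spec(fl$lambda, fl$psi, fl$theta, lower = fl$lower)
    },
    trp_g = {
      obs <- c(trp, bis)
      lat <- c("trp", "g")
      lambda <- matrix(0, 7, 2, dimnames = list(obs, lat))
      lambda[1:4, "trp"] <- FREE
      lambda[5:7, "g"] <- g_measurement(first_fixed = TRUE)
      beta <- matrix(0, 2, 2, dimnames = list(lat, lat))
      beta["g", "trp"] <- FREE
      psi <- matrix(c(1, 0, 0, FREE), 2, 2, dimnames = list(lat, lat))
      cov_model_spec(lambda, psi, diag_theta(obs), beta)
    },
    ss_g = {
      obs <- c(mdd, bis)
      lat <- c("ssc", "ssi", "g")
      fl <- fixed_links_parts()
      lambda <- matrix(0, 7, 3, dimnames = list(obs, lat))
      lambda[1:4, 1:2] <- fl$lambda
      lambda[5:7, "g"] <- g_measurement(first_fixed = TRUE)
      beta <- matrix(0, 3, 3, dimnames = list(lat, lat))
      beta["g", "ssc"] <- beta["g", "ssi"] <- FREE
      psi <- diag(c(FREE, FREE, FREE)); dimnames(psi) <- list(lat, lat)
      theta <- block_diag(fl$theta, diag_theta(bis))
      lt <- matrix(NA_real_, 7, 7); lt[1, 1] <- 1e-6; lt[4, 4] <- 1e-6
      cov_model_spec(lambda, psi, theta, beta, lower = list(theta = lt))
    },
    trp_ss_corr = {
      obs <- c(trp, mdd)
      lat <- c("trp", "ssc", "ssi")
      fl <- fixed_links_parts()
      lambda <- matrix(0, 8, 3, dimnames = list(obs, lat))
      lambda[1:4, "trp"] <- FREE
      lambda[5:8, 2:3] <- fl$lambda
      psi <- matrix(c(1, FREE, FREE,
                      FREE, FREE, 0,
                      FREE, 0, FREE), 3, 3, dimnames = list(lat, lat))
      theta <- block_diag(diag_theta(trp), fl$theta)
      lt <- matrix(NA_real_, 8, 8); lt[5, 5] <- 1e-6; lt[8, 8] <- 1e-6
      cov_model_spec(lambda, psi, theta, lower = list(theta = lt))
    },
    combined = {
      obs <- c(trp, mdd, bis)
      lat <- c("trp", "ssc", "ssi", "g")
      fl <- fixed_links_parts()
      lambda <- matrix(0, 11, 4, dimnames = list(obs, lat))
      lambda[1:4, "trp"] <- FREE
      lambda[5:8, 2:3] <- fl$lambda
      lambda[9:11, "g"] <- g_measurement(first_fixed = TRUE)
      beta <- matrix(0, 4, 4, dimnames = list(lat, lat))
      beta["g", c("trp", "ssc", "ssi")] <- FREE
      psi <- matrix(0, 4, 4, dimnames = list(lat, lat))
      psi["trp", "trp"] <- 1
      psi["ssc", "ssc"] <- psi["ssi", "ssi"] <- psi["g", "g"] <- FREE
      psi["trp", "ssc"] <- psi["ssc", "trp"] <- FREE
      psi["trp", "ssi"] <- psi["ssi", "trp"] <- FREE
      theta <- block_diag(diag_theta(trp), fl$theta, diag_theta(bis))
      lt <- matrix(NA_real_, 11, 11); lt[5, 5] <- 1e-6; lt[8, 8] <- 1e-6
      cov_model_spec(lambda, psi, theta, beta, lower = list(theta = lt))
    },
    stop("unknown model name: ", name)
  )
}

#' Names of all registered study models
#' @return character vector of registry names.
#' @export
model_registry <- function() {
  c("g_cfa", "trp_cfa", "ss_congeneric", "ss_fixedlinks_base",
    "ss_fixedlinks", "trp_g", "ss_g", "trp_ss_corr", "combined")
}
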
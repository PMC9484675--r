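#' Default latent correlation matrix
#'
#' Correlations among the four latent traits that drive the simulated
#' battery: temporal imprecision (`trp`, higher = poorer timing), the
#' size-invariant motion-threshold component (`ssc`), the size-increasing
#' suppression component (`ssi`), and general intelligence (`g`).
#' Defaults place `trp`--`ssc` at .353 and `trp`--`ssi` at .180, give the
#' `g` factor a standardized association of `beta_trp_g` with `trp`, and
#' derive the `g` correlations of `ssc`/`ssi` by full mediation through
#' `trp` (`beta_trp_g * r_trp_ssc`, etc.). `ssc` and `ssi` are orthogonal.
#'
#' @param beta_trp_g standardized association between timing imprecision
#'   and `g` (negative: poorer timing, lower intelligence).
#' @param r_trp_ssc,r_trp_ssi correlations of `trp` with the two
#'   motion-threshold components.
#' @return a 4x4 correlation matrix with dimnames
#'   `c("trp","ssc","ssi","g")`.
#' @export
default_latent_corr <- function(beta_trp_g = -0.535, r_trp_ssc = 0.353,
                                r_trp_ssi = 0.180) {
  nm <- c("trp", "ssc", "ssi", "g")
  r <- diag(4)
  dimnames(r) <- list(nm, nm)
  r["trp", "ssc"] <- r["ssc", "trp"] <- r_trp_ssc
  r["trp", "ssi"] <- r["ssi", "trp"] <- r_trp_ssi
  r["trp", "g"] <- r["g", "trp"] <- beta_trp_g
  r["ssc", "g"] <- r["g", "ssc"] <- beta_trp_g * r_trp_ssc
  r["ssi", "g"] <- r["g", "ssi"] <- beta_trp_g * r_trp_ssi
  r
}

#' Specify a synthetic observer population
#'
#' Collects every generative constant of the simulated study. The defaults
#' describe a population whose latent structure matches the measurement
#' models fitted downstream: the four log10 motion-direction duration
#' thresholds decompose into a constant component (loading 1,1,1,1) and a
#' linearly increasing component (loading 0,1,2,3); the four timing-task
#' parameters load on a single temporal-imprecision factor; and the three
#' intelligence composites load on a single `g` factor.
#'
#' Units and defaults:
#' * `base_log_threshold`: log10 ms threshold at the smallest size
#'   (default `log10(44.69 / 2.5)`, i.e. about 17.9 ms).
#' * `si_mean`: population mean spatial suppression index (largest minus
#'   smallest log10 threshold), default 0.29; the per-size mean increase
#'   is `si_mean / 3`.
#' * `ssc_sd`, `ssi_sd`: SDs of the constant and increasing latent
#'   components on the log10-ms scale (defaults `sqrt(.022)`,
#'   `sqrt(.003)`).
#' * `mdd_noise_sd`: SD of the size-specific residual on each log10
#'   threshold.
#' * `timing_base`, `timing_sd`: location/scale (ms, except the
#'   generalization kernel which is a ms spread) of the four timing-task
#'   observer parameters; `timing_loadings` are their standardized
#'   loadings on the imprecision factor.
#' * `bis_loadings`: standardized loadings of the capacity/speed/memory
#'   composites on `g` (defaults reproduce inter-composite correlations
#'   .51/.46/.39).
#'
#' @param n_subjects number of simulated subjects (>= 2).
#' @param latent_corr 4x4 latent correlation matrix over
#'   `(trp, ssc, ssi, g)`; see [default_latent_corr()].
#' @param base_log_threshold log10-ms intercept of the motion threshold at
#'   the smallest stimulus size.
#' @param si_mean population mean of the spatial suppression index.
#' @param ssc_sd,ssi_sd latent SDs (log10 ms) of the constant and
#'   increasing threshold components.
#' @param mdd_noise_sd residual SD (log10 ms) per threshold condition.
#' @param timing_base,timing_sd,timing_loadings named numeric vectors over
#'   `c("dde","ddf","tg","rp")`.
#' @param bis_loadings loadings of the three intelligence composites on g.
#' @param lapse_rate observer lapse rate in \[0, 0.1\].
#' @param motion_slope Weibull slope of the motion psychometric function.
#' @param seed integer seed used by [sample_population()].
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 273,
                            latent_corr = default_latent_corr(),
                            base_log_threshold = log10(44.69 / 2.5),
                            si_mean = 0.29,
                            ssc_sd = sqrt(0.022),
                            ssi_sd = sqrt(0.003),
                            mdd_noise_sd = 0.05,
                            timing_base = c(dde = 18.33, ddf = 8.81,
                                            tg = 6.6, rp = 55.86),
                            timing_sd = c(dde = 8.22, ddf = 3.26,
                                          tg = 2.0, rp = 22.43),
                            timing_loadings = c(dde = 0.52, ddf = 0.63,
                                                tg = 0.51, rp = 0.34),
                            bis_loadings = c(capacity = 0.776,
                                             speed = 0.658,
                                             memory = 0.593),
                            lapse_rate = 0.01,
                            motion_slope = 3.5,
                            seed = 1L) {
  stopifnot(n_subjects >= 2)
  check_corr_matrix(latent_corr)
  stopifnot(ssc_sd >= 0, ssi_sd >= 0, mdd_noise_sd >= 0,
            all(timing_sd >= 0), lapse_rate >= 0, lapse_rate <= 0.1,
            motion_slope > 0,
            all(abs(timing_loadings) <= 1), all(abs(bis_loadings) <= 1))
  tasks <- c("dde", "ddf", "tg", "rp")
  stopifnot(all(tasks %in% names(timing_base)),
            all(tasks %in% names(timing_sd)),
            all(tasks %in% names(timing_loadings)))
  spec <- list(n_subjects = as.integer(n_subjects),
               latent_corr = latent_corr,
               base_log_threshold = base_log_threshold,
               si_mean = si_mean,
               ssc_sd = ssc_sd, ssi_sd = ssi_sd,
               mdd_noise_sd = mdd_noise_sd,
               timing_base = timing_base[tasks],
               timing_sd = timing_sd[tasks],
               timing_loadings = timing_loadings[tasks],
               bis_loadings = bis_loadings,
               lapse_rate = lapse_rate,
               motion_slope = motion_slope,
               seed = as.integer(seed))
  class(spec) <- "population_spec"
  spec
}

# loading of a single subtest on g such that the mean of six z-scored
# subtests correlates b with g: a^2 = b^2 / (6 - 5 b^2)
subtest_loading <- function(b) sqrt(b^2 / (6 - 5 * b^2))

#' Sample a population of simulated observers
#'
#' Draws latent traits from the specified correlation structure and maps
#' them to observer parameters: per-size log10 motion thresholds
#' (`base + slope * w + ssc_sd * eta_ssc + ssi_sd * w * eta_ssi + eps`,
#' with size weights `w = 0,1,2,3`), timing-task parameters that worsen
#' with the imprecision trait, and 18 intelligence subtest scores (six per
#' composite) loading on `g`. Timing parameters are floored at small
#' positive values so that every observer remains simulable.
#'
#' @param spec a [population_spec()].
#' @return a list of class `population` with elements
#'   * `latents`: data frame `subject, trp, ssc, ssi, g`;
#'   * `observers`: data frame of observer parameters, one row per subject
#'     (`mdd_log_threshold_1..4`, `dd_jnd_empty`, `dd_jnd_filled`,
#'     `tg_sd`, `rp_jnd`, `psychometric_slope`, `lapse_rate`);
#'   * `bis_subtests`: `n x 18` matrix of raw subtest scores;
#'   * `spec`: the input specification.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  eta <- rmvn(n, spec$latent_corr)
  colnames(eta) <- colnames(spec$latent_corr)

  w <- 0:3
  size_mean <- spec$base_log_threshold + (spec$si_mean / 3) * w
  eps <- matrix(stats::rnorm(n * 4, sd = spec$mdd_noise_sd), n, 4)
  mdd <- matrix(size_mean, n, 4, byrow = TRUE) +
    spec$ssc_sd * eta[, "ssc"] %o% rep(1, 4) +
    spec$ssi_sd * eta[, "ssi"] %o% w + eps

  timing <- sapply(c("dde", "ddf", "tg", "rp"), function(task) {
    lam <- spec$timing_loadings[[task]]
    z <- lam * eta[, "trp"] + sqrt(1 - lam^2) * stats::rnorm(n)
    spec$timing_base[[task]] + spec$timing_sd[[task]] * z
  })
  floors <- c(dde = 1, ddf = 1, tg = 0.5, rp = 1)
  timing <- pmax(timing, matrix(floors, n, 4, byrow = TRUE))

  a <- subtest_loading(spec$bis_loadings)             # one loading per bundle
  bundle <- rep(seq_len(3), each = 6)
  subtests <- sapply(seq_len(18), function(j) {
    aj <- a[bundle[j]]
    aj * eta[, "g"] + sqrt(1 - aj^2) * stats::rnorm(n)
  })
  colnames(subtests) <- paste0(rep(c("capacity", "speed", "memory"), each = 6),
                               "_", rep(1:6, 3))

  observers <- data.frame(
    subject = seq_len(n),
    mdd_log_threshold_1 = mdd[, 1], mdd_log_threshold_2 = mdd[, 2],
    mdd_log_threshold_3 = mdd[, 3], mdd_log_threshold_4 = mdd[, 4],
    dd_jnd_empty = timing[, "dde"], dd_jnd_filled = timing[, "ddf"],
    tg_sd = timing[, "tg"], rp_jnd = timing[, "rp"],
    psychometric_slope = spec$motion_slope,
    lapse_rate = spec$lapse_rate)

  structure(list(latents = data.frame(subject = seq_len(n),
                                      trp = eta[, "trp"], ssc = eta[, "ssc"],
                                      ssi = eta[, "ssi"], g = eta[, "g"]),
                 observers = observers,
                 bis_subtests = subtests,
                 spec = spec),
            class = "population")
}

#' Expected temporal-generalization dispersion index for a given kernel
#'
#' Closed-form expectation of the response-dispersion index for an
#' observer with Gaussian generalization spread `sd`: the per-duration
#' yes-probabilities stand in for the limiting relative frequencies, so
#' presentation counts cancel.
#'
#' @param sd generalization kernel spread (ms).
#' @param lapse lapse rate.
#' @param durations the seven test durations (ms).
#' @param standard the standard duration (ms).
#' @return expected dispersion index in \[0, 1\].
#' @export
tg_expected_index <- function(sd, lapse = 0.01,
                              durations = c(42, 53, 64, 75, 86, 97, 108),
                              standard = 75) {
  sapply(sd, function(s) {
    p <- pf_generalization(durations, s, standard, lapse)
    p[durations == standard] / sum(p)
  })
}
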
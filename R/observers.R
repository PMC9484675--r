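#' Single-trial responses of a simulated observer
#'
#' Each function draws one Bernoulli response from the observer's
#' psychometric function using the current R random number stream.
#' `obs` is one row of the `observers` data frame produced by
#' [sample_population()] (a list or one-row data frame with the observer
#' parameter fields).
#'
#' @param obs observer parameters (one-row data frame or list).
#' @name respond
NULL

as_observer <- function(obs) {
  obs <- as.list(obs)
  need <- c("mdd_log_threshold_1", "mdd_log_threshold_2",
            "mdd_log_threshold_3", "mdd_log_threshold_4",
            "dd_jnd_empty", "dd_jnd_filled", "tg_sd", "rp_jnd",
            "psychometric_slope", "lapse_rate")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("observer is missing fields: ", paste(miss, collapse = ", "))
  stopifnot(obs$lapse_rate >= 0, obs$lapse_rate <= 0.1,
            obs$psychometric_slope > 0)
  obs
}

#' @describeIn respond correct/incorrect motion-direction judgement for a
#'   stimulus of size index `size_index` (1..4, smallest to largest) shown
#'   for `log_duration` (log10 ms).
#' @param size_index stimulus size condition, 1 to 4.
#' @param log_duration log10 presentation time (ms).
#' @export
respond_motion <- function(obs, size_index, log_duration) {
  obs <- as_observer(obs)
  stopifnot(size_index %in% 1:4)
  thr <- obs[[paste0("mdd_log_threshold_", size_index)]]
  p <- pf_weibull_2afc(log_duration, thr, slope = obs$psychometric_slope,
                       lapse = obs$lapse_rate)
  stats::runif(1) < p
}

#' @describeIn respond correct/incorrect "which interval was longer"
#'   judgement for a comparison of `comparison_ms` against a
#'   `standard_ms` standard.
#' @param standard_ms standard interval duration (ms), default 50.
#' @param comparison_ms comparison interval duration (ms), must differ
#'   from the standard.
#' @param variant `"empty"` or `"filled"` interval marker.
#' @export
respond_duration_discrimination <- function(obs, comparison_ms,
                                            standard_ms = 50,
                                            variant = c("empty", "filled")) {
  obs <- as_observer(obs)
  variant <- match.arg(variant)
  stopifnot(comparison_ms > 0)
  if (comparison_ms == standard_ms)
    stop("comparison equal to standard: correctness is undefined")
  jnd <- if (variant == "empty") obs$dd_jnd_empty else obs$dd_jnd_filled
  p <- pf_logistic_delta(abs(comparison_ms - standard_ms), jnd,
                         lapse = obs$lapse_rate)
  stats::runif(1) < p
}

#' @describeIn respond "yes, this was the standard" judgement for a test
#'   duration from the generalization set.
#' @param duration_ms test duration; must be one of
#'   42, 53, 64, 75, 86, 97, 108 ms.
#' @export
respond_generalization <- function(obs, duration_ms) {
  obs <- as_observer(obs)
  if (!duration_ms %in% c(42, 53, 64, 75, 86, 97, 108))
    stop("duration must be one of 42, 53, 64, 75, 86, 97, 108 ms")
  p <- pf_generalization(duration_ms, obs$tg_sd, lapse = obs$lapse_rate)
  stats::runif(1) < p
}

#' @describeIn respond detection of rhythmic irregularity when one
#'   beat-to-beat interval is lengthened by `deviant_ms_x` ms.
#' @param deviant_ms_x lengthening of the deviant interval (ms), >= 0.
#' @export
respond_rhythm <- function(obs, deviant_ms_x) {
  obs <- as_observer(obs)
  stopifnot(deviant_ms_x >= 0)
  p <- pf_logistic_delta(deviant_ms_x, obs$rp_jnd, lapse = obs$lapse_rate)
  stats::runif(1) < p
}
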
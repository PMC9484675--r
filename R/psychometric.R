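#' Psychometric functions for simulated observers
#'
#' Three parametric families cover the tasks in the battery:
#' * a Weibull on log10 duration for two-alternative motion-direction
#'   judgements (chance 0.5), anchored so that the probability of a correct
#'   response equals `target_p` exactly at `threshold`;
#' * a logistic (tanh) function of the absolute duration difference for
#'   interval discrimination and irregularity detection, anchored so that
#'   performance equals `target_p` at `jnd`;
#' * a Gaussian similarity kernel for "same duration?" generalization
#'   judgements, peaked at the standard duration.
#'
#' All functions are vectorised over their first argument and over
#' `threshold`/`jnd`, which is what the QUEST grid update relies on.
#'
#' @name psychometric
NULL

#' @describeIn psychometric probability of a correct 2AFC motion-direction
#'   response at log10 duration `x` for an observer with the given threshold.
#' @param x log10 stimulus duration (ms).
#' @param threshold log10 duration at which performance equals `target_p`.
#' @param slope Weibull slope (unitless, on the log10 axis).
#' @param chance lower asymptote (guessing rate).
#' @param lapse lapse rate; the upper asymptote is `1 - lapse`.
#' @param target_p performance level that defines the threshold.
#' @export
pf_weibull_2afc <- function(x, threshold, slope = 3.5, chance = 0.5,
                            lapse = 0.01, target_p = 0.82) {
  stopifnot(slope > 0, target_p > chance, target_p < 1 - lapse)
  # shift so that p(threshold) == target_p
  q <- (1 - lapse - target_p) / (1 - lapse - chance)
  shift <- log10(-log(q)) / slope
  p <- 1 - lapse - (1 - lapse - chance) * exp(-10^(slope * (x - threshold + shift)))
  pmin(pmax(p, chance), 1 - lapse)
}

#' @describeIn psychometric probability of a correct duration-difference
#'   judgement at absolute difference `delta` (ms) for an observer whose
#'   just-noticeable difference is `jnd` (performance `target_p` at
#'   `delta == jnd`).
#' @param delta absolute duration difference (ms), non-negative.
#' @param jnd difference (ms) at which performance equals `target_p`.
#' @export
pf_logistic_delta <- function(delta, jnd, lapse = 0.01, target_p = 0.75) {
  stopifnot(all(jnd > 0), target_p > 0.5, target_p < 1 - lapse)
  # p(delta) = 0.5 + (0.5 - lapse) * tanh(delta / (2 s)), s anchored at jnd
  s <- jnd / (2 * atanh((target_p - 0.5) / (0.5 - lapse)))
  p <- 0.5 + (0.5 - lapse) * tanh(abs(delta) / (2 * s))
  pmin(pmax(p, 0.5), 1 - lapse)
}

#' @describeIn psychometric probability of a "yes, this was the standard"
#'   response to duration `d` (ms) when the standard is `standard` and the
#'   observer's duration representation has Gaussian spread `sd` (ms).
#'   With `sd = 0` the observer answers yes iff `d == standard` (up to
#'   lapses); as `sd` grows, all durations become equally acceptable.
#' @param d presented duration (ms).
#' @param sd spread of the generalization kernel (ms).
#' @param standard memorised standard duration (ms).
#' @export
pf_generalization <- function(d, sd, standard = 75, lapse = 0.01) {
  stopifnot(all(sd >= 0))
  n <- max(length(d), length(sd))
  d <- rep_len(d, n); sd <- rep_len(sd, n)
  kern <- ifelse(sd == 0, as.numeric(d == standard),
                 exp(-(d - standard)^2 / (2 * pmax(sd, .Machine$double.eps)^2)))
  lapse + (1 - 2 * lapse) * kern
}
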
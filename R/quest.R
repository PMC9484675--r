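#' Bayesian adaptive threshold procedure (QUEST)
#'
#' Grid-based implementation of the classic Bayesian adaptive procedure:
#' a posterior over candidate log10-ms thresholds is maintained on a fixed
#' grid, updated after every trial by the likelihood of the observed
#' response under an assumed Weibull psychometric family, and summarised
#' by its mean for both trial placement and the final threshold estimate.
#' The first trial is placed at a fixed initial duration (default 80 ms).
#'
#' @param grid strictly increasing vector of candidate log10-ms
#'   thresholds.
#' @param target_p targeted probability correct defining the threshold.
#' @param slope,chance,lapse assumed psychometric parameters.
#' @param initial_log_duration placement of the first trial (log10 ms).
#' @param prior `"uniform"` or a numeric vector of prior weights over
#'   `grid`.
#' @return a `quest_state` object.
#' @export
quest_init <- function(grid = seq(log10(2), log10(500), by = 0.01),
                       target_p = 0.82, slope = 3.5, chance = 0.5,
                       lapse = 0.01, initial_log_duration = log10(80),
                       prior = "uniform") {
  stopifnot(all(diff(grid) > 0), target_p > chance, target_p < 1 - lapse)
  lp <- if (identical(prior, "uniform")) rep(0, length(grid)) else {
    stopifnot(length(prior) == length(grid), all(prior > 0))
    log(prior)
  }
  lp <- lp - log(sum(exp(lp - max(lp)))) - max(lp)
  structure(list(grid = grid, log_posterior = lp, target_p = target_p,
                 slope = slope, chance = chance, lapse = lapse,
                 initial_log_duration = initial_log_duration,
                 trial_count = 0L, degenerate = FALSE),
            class = "quest_state")
}

quest_posterior <- function(state) {
  w <- exp(state$log_posterior - max(state$log_posterior))
  w / sum(w)
}

#' Next QUEST trial placement
#'
#' Returns the fixed initial duration before any update, then the
#' posterior mean of the threshold, clamped to the grid bounds. A
#' posterior with essentially all mass on one grid bound flags the state
#' as degenerate.
#'
#' @param state a `quest_state`.
#' @return placement in log10 ms (with the possibly flagged state in
#'   attribute `"state"`).
#' @export
quest_next_level <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  if (state$trial_count == 0L) return(structure(state$initial_log_duration,
                                                state = state))
  w <- quest_posterior(state)
  edge <- max(w[1], w[length(w)])
  if (edge > 0.99) state$degenerate <- TRUE
  lvl <- sum(w * state$grid)
  lvl <- min(max(lvl, state$grid[1]), state$grid[length(state$grid)])
  structure(lvl, state = state)
}

#' Update the QUEST posterior with one response
#'
#' Adds the log-likelihood of the observed response at each grid point
#' (under the assumed Weibull family anchored at `target_p`) and
#' renormalises.
#'
#' @param state a `quest_state`.
#' @param level tested level (log10 ms).
#' @param correct logical response.
#' @return the updated `quest_state`.
#' @export
quest_update <- function(state, level, correct) {
  stopifnot(inherits(state, "quest_state"), is.finite(level))
  p <- pf_weibull_2afc(level, state$grid, slope = state$slope,
                       chance = state$chance, lapse = state$lapse,
                       target_p = state$target_p)
  state$log_posterior <- state$log_posterior +
    if (isTRUE(correct)) log(p) else log1p(-p)
  m <- max(state$log_posterior)
  state$log_posterior <- state$log_posterior -
    (m + log(sum(exp(state$log_posterior - m))))
  state$trial_count <- state$trial_count + 1L
  state
}

#' QUEST threshold estimate
#'
#' Posterior mean of the threshold on the log10-ms grid. Requires at
#' least one update.
#'
#' @param state a `quest_state`.
#' @return estimate in log10 ms.
#' @export
quest_estimate <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  if (state$trial_count < 1L) stop("no updates yet: estimate undefined")
  sum(quest_posterior(state) * state$grid)
}

#' Run a complete QUEST series against a response function
#'
#' @param respond function of one argument (log10 ms) returning a logical
#'   correctness.
#' @param n_trials number of trials (default 22).
#' @param state initial state from [quest_init()].
#' @return list with `estimate` (log10 ms), final `state`, and a
#'   `trials` data frame (`trial, level, correct`).
#' @export
quest_run <- function(respond, n_trials = 22, state = quest_init()) {
  levels <- numeric(n_trials)
  correct <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    lvl <- quest_next_level(state)
    state <- attr(lvl, "state")
    levels[t] <- as.numeric(lvl)
    correct[t] <- respond(levels[t])
    state <- quest_update(state, levels[t], correct[t])
  }
  list(estimate = quest_estimate(state), state = state,
       trials = data.frame(trial = seq_len(n_trials), level = levels,
                           correct = correct))
}
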
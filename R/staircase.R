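#' Weighted up-down staircase
#'
#' Asymmetric-step staircase whose equilibrium probability correct is
#' `step_up / (step_up + step_down)`: the tracked level decreases by
#' `step_down` after a correct response and increases by `step_up` after
#' an incorrect one. Steps may switch once at a scheduled trial (e.g.
#' from 9/3 ms to 6/2 ms at the seventh trial); the step applied after a
#' response is the one in force for the trial that was just answered.
#' Levels are clamped at a floor to avoid non-physical differences.
#'
#' @param start_level level of the first trial (ms).
#' @param steps list of one or two `c(up, down)` step pairs (ms).
#' @param phase_switch index of the first trial that uses the second step
#'   pair (default 7; ignored with a single pair).
#' @param series_length planned number of trials (default 32).
#' @param floor minimum level (ms, default 1).
#' @return a `staircase_state` object.
#' @export
staircase_init <- function(start_level, steps = list(c(up = 9, down = 3),
                                                     c(up = 6, down = 2)),
                           phase_switch = 7, series_length = 32, floor = 1) {
  steps <- lapply(steps, function(s) {
    s <- unname(s)
    stopifnot(length(s) == 2, all(s > 0))
    c(up = s[1], down = s[2])
  })
  stopifnot(start_level >= floor, length(steps) %in% 1:2)
  structure(list(levels = start_level, responses = logical(0),
                 steps = steps, phase_switch = phase_switch,
                 series_length = as.integer(series_length), floor = floor),
            class = "staircase_state")
}

staircase_trial <- function(state) length(state$responses) + 1L

step_for_trial <- function(state, trial) {
  if (length(state$steps) == 1L || trial < state$phase_switch)
    state$steps[[1]] else state$steps[[2]]
}

#' Record a response and compute the next staircase level
#'
#' @param state a `staircase_state`.
#' @param correct logical response on the current trial.
#' @return the updated state, with the next level appended.
#' @export
staircase_next <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"))
  t <- staircase_trial(state)
  if (t > state$series_length) stop("series already complete")
  st <- step_for_trial(state, t)
  lvl <- state$levels[t] + if (isTRUE(correct)) -st[["down"]] else st[["up"]]
  state$responses <- c(state$responses, isTRUE(correct))
  state$levels <- c(state$levels, max(lvl, state$floor))
  state
}

#' Staircase threshold from the last twenty trials
#'
#' Mean of the levels presented on the last twenty trials of a completed
#' series.
#'
#' @param state a completed `staircase_state`.
#' @param last number of trailing trials to average (default 20).
#' @return threshold on the level scale (ms).
#' @export
staircase_threshold <- function(state, last = 20) {
  stopifnot(inherits(state, "staircase_state"))
  n <- length(state$responses)
  if (n < state$series_length)
    stop(sprintf("series incomplete: %d of %d trials", n, state$series_length))
  lv <- state$levels[seq_len(state$series_length)]
  mean(utils::tail(lv, last))
}

#' Run a complete staircase series against a response function
#'
#' @param respond function of one argument (level, ms) returning logical
#'   correctness.
#' @param state initial state from [staircase_init()].
#' @param n_trials number of trials (defaults to the state's series
#'   length).
#' @return list with the final `state` and a `trials` data frame.
#' @export
staircase_run <- function(respond, state, n_trials = state$series_length) {
  for (t in seq_len(n_trials)) {
    lvl <- state$levels[t]
    state <- staircase_next(state, respond(lvl))
  }
  list(state = state,
       trials = data.frame(trial = seq_len(n_trials),
                           level = state$levels[seq_len(n_trials)],
                           correct = state$responses[seq_len(n_trials)]))
}

#' Interleave two equally long trial series
#'
#' Produces a randomized but balanced schedule over two series, each of
#' which keeps its own internal trial order, and counterbalances the
#' order of standard and comparison interval 50/50 within each series.
#'
#' @param n_a,n_b series lengths (must be equal; even counts are required
#'   for exact counterbalancing, odd counts are flagged).
#' @return data frame `trial, series, within_trial, standard_first`.
#' @export
interleave_series <- function(n_a, n_b) {
  if (n_a != n_b) stop("series lengths must be equal")
  series <- sample(rep(1:2, times = c(n_a, n_b)))
  sf <- function(n) {
    if (n %% 2 != 0)
      warning("odd series length: standard/comparison order cannot balance exactly")
    sample(rep(c(TRUE, FALSE), length.out = n))
  }
  sfa <- sf(n_a); sfb <- sf(n_b)
  within <- integer(n_a + n_b)
  within[series == 1] <- seq_len(n_a)
  within[series == 2] <- seq_len(n_b)
  standard_first <- ifelse(series == 1, sfa[within], sfb[within])
  data.frame(trial = seq_len(n_a + n_b), series = series,
             within_trial = within, standard_first = standard_first)
}

#' Equilibrium probability correct of a weighted up-down rule
#'
#' Solves `p * step_down = (1 - p) * step_up` for the probability at
#' which the expected level movement vanishes.
#'
#' @param step_up increase after an incorrect response (ms).
#' @param step_down decrease after a correct response (ms).
#' @return equilibrium probability correct.
#' @export
staircase_equilibrium_p <- function(step_up, step_down) {
  stopifnot(step_up > 0, step_down > 0)
  step_up / (step_up + step_down)
}
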
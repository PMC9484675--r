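#' Aggregate repeated threshold estimates by dropping extremes
#'
#' Discards the single highest and single lowest of six (or more)
#' estimates and averages the remainder.
#'
#' @param estimates numeric vector of at least 3 estimates.
#' @return trimmed mean.
#' @export
aggregate_estimates <- function(estimates) {
  stopifnot(length(estimates) >= 3)
  s <- sort(estimates)
  mean(s[-c(1, length(s))])
}

#' Run the spatial-suppression session for one observer
#'
#' Three blocks, each yielding two independent QUEST estimates per
#' stimulus size (22 trials per estimate, 44 per size per block, 528
#' trials in total over the four sizes). Per size, the six estimates are
#' reduced by discarding the highest and lowest and averaging the
#' remaining four.
#'
#' @param obs observer parameters (row of [sample_population()]'s
#'   `observers`).
#' @param blocks number of blocks (default 3).
#' @param estimates_per_block QUEST runs per size per block (default 2).
#' @param trials_per_estimate trials per QUEST run (default 22).
#' @param quest_args extra arguments to [quest_init()].
#' @return list with `thresholds` (4 log10-ms values, smallest to
#'   largest size), `si`, and the `estimates` matrix (4 x runs).
#' @export
run_spatial_suppression <- function(obs, blocks = 3, estimates_per_block = 2,
                                    trials_per_estimate = 22,
                                    quest_args = list()) {
  obs <- as_observer(obs)
  n_est <- blocks * estimates_per_block
  if (n_est < 6) stop("need at least 6 estimates per size (3 blocks x 2)")
  est <- matrix(NA_real_, 4, n_est)
  for (b in seq_len(blocks)) for (e in seq_len(estimates_per_block))
    for (s in 1:4) {
      state <- do.call(quest_init, quest_args)
      run <- quest_run(function(lvl) respond_motion(obs, s, lvl),
                       n_trials = trials_per_estimate, state = state)
      est[s, (b - 1) * estimates_per_block + e] <- run$estimate
    }
  thr <- apply(est, 1, aggregate_estimates)
  list(thresholds = thr, si = spatial_suppression_index(thr), estimates = est)
}

#' Spatial suppression index
#'
#' Difference between the log10-ms threshold at the largest (7.2 deg) and
#' the smallest (1.8 deg) stimulus size.
#'
#' @param thresholds numeric vector of 4 log10-ms thresholds, ordered from
#'   smallest to largest size.
#' @return the index (log10 units).
#' @export
spatial_suppression_index <- function(thresholds) {
  stopifnot(length(thresholds) == 4, all(is.finite(thresholds)))
  thresholds[4] - thresholds[1]
}

#' Run one duration-discrimination session
#'
#' Two interleaved weighted up-down series of 32 trials (one tracking the
#' comparison-longer, one the comparison-shorter side of the 50-ms
#' standard), steps 9/3 ms for the first six trials and 6/2 ms
#' afterwards. Each series' threshold is the mean level over its last 20
#' trials; expressed on the comparison scale these give the 75% and 25%
#' points, and the difference limen is half their distance.
#'
#' @param obs observer parameters.
#' @param variant `"empty"` or `"filled"` intervals.
#' @param standard_ms standard duration (ms).
#' @param start_delta initial standard-comparison difference (ms).
#' @return list with `x25`, `x75` (ms), `dl` (ms), `flagged` (series that
#'   did not straddle the standard), and the two series' trial frames.
#' @export
run_duration_discrimination <- function(obs, variant = c("empty", "filled"),
                                        standard_ms = 50, start_delta = 30) {
  obs <- as_observer(obs)
  variant <- match.arg(variant)
  sched <- interleave_series(32, 32)
  st <- list(staircase_init(start_delta), staircase_init(start_delta))
  for (i in seq_len(nrow(sched))) {
    s <- sched$series[i]
    delta <- st[[s]]$levels[staircase_trial(st[[s]])]
    comp <- if (s == 1) standard_ms + delta else standard_ms - delta
    comp <- max(comp, 1)
    correct <- respond_duration_discrimination(obs, comp, standard_ms, variant)
    st[[s]] <- staircase_next(st[[s]], correct)
  }
  d75 <- staircase_threshold(st[[1]])
  d25 <- staircase_threshold(st[[2]])
  x75 <- standard_ms + d75
  x25 <- standard_ms - d25
  list(x25 = x25, x75 = x75, dl = (x75 - x25) / 2,
       flagged = !(x25 <= standard_ms && standard_ms <= x75),
       series_longer = st[[1]], series_shorter = st[[2]])
}

#' Run one temporal-generalization session
#'
#' Eight blocks; within each, the 75-ms standard is presented twice and
#' each of the six alternatives (42, 53, 64, 86, 97, 108 ms) once, in
#' random order. The response-dispersion index divides the relative
#' "yes" frequency to the standard (over its 16 presentations) by the sum
#' of the relative "yes" frequencies of all seven durations (8
#' presentations each for the alternatives). The inverted value
#' `1 - index` is the analysis-direction score (higher = poorer).
#'
#' @param obs observer parameters.
#' @param blocks number of blocks (default 8).
#' @return list with `index`, `inverted`, `yes_counts`, and `flagged`
#'   (`TRUE` when no "yes" at all was given; the index is then set to the
#'   worst value 0).
#' @export
run_temporal_generalization <- function(obs, blocks = 8) {
  obs <- as_observer(obs)
  durations <- c(42, 53, 64, 75, 86, 97, 108)
  pres <- stats::setNames(rep(0L, 7), durations)
  yes <- stats::setNames(rep(0L, 7), durations)
  for (b in seq_len(blocks)) {
    block <- sample(c(75, 75, setdiff(durations, 75)))
    for (d in block) {
      key <- as.character(d)
      pres[key] <- pres[key] + 1L
      if (respond_generalization(obs, d)) yes[key] <- yes[key] + 1L
    }
  }
  rf <- yes / pres
  if (sum(yes) == 0L) {
    return(list(index = 0, inverted = 1, yes_counts = yes, flagged = TRUE))
  }
  idx <- rf["75"] / sum(rf)
  list(index = unname(idx), inverted = unname(1 - idx),
       yes_counts = yes, flagged = FALSE)
}

#' Run one rhythm-perception session
#'
#' Two interleaved weighted up-down series of 32 trials on the deviant
#' lengthening x (initially 20 ms; deviant at the third vs fourth
#' beat-to-beat interval), with a 4-ms decrease after a correct
#' "irregular" detection and a 12-ms increase after a miss (equilibrium
#' 12/16 = 75% correct). Each series' 75% threshold is the mean level
#' over its last 20 trials; the output averages the two.
#'
#' @param obs observer parameters.
#' @param start_x initial deviant lengthening (ms).
#' @return list with `threshold` (ms), the per-series thresholds, and the
#'   two series states.
#' @export
run_rhythm_perception <- function(obs, start_x = 20) {
  obs <- as_observer(obs)
  sched <- interleave_series(32, 32)
  st <- lapply(1:2, function(i)
    staircase_init(start_x, steps = list(c(up = 12, down = 4))))
  for (i in seq_len(nrow(sched))) {
    s <- sched$series[i]
    x <- st[[s]]$levels[staircase_trial(st[[s]])]
    st[[s]] <- staircase_next(st[[s]], respond_rhythm(obs, x))
  }
  thr <- vapply(st, staircase_threshold, numeric(1))
  list(threshold = mean(thr), series_thresholds = thr, series = st)
}

#' Score the intelligence-test battery
#'
#' Z-standardizes each of 18 subtest score columns over subjects, then
#' averages each six-subtest bundle into its composite (capacity, speed,
#' memory).
#'
#' @param subtest_scores numeric matrix or data frame, subjects x 18
#'   subtests ordered capacity 1-6, speed 1-6, memory 1-6 (or supply
#'   `bundle`).
#' @param bundle integer vector of length 18 assigning each column to
#'   composite 1, 2 or 3.
#' @return data frame with `bis_capacity`, `bis_speed`, `bis_memory`.
#' @export
score_bis <- function(subtest_scores, bundle = rep(1:3, each = 6)) {
  x <- as.matrix(subtest_scores)
  stopifnot(ncol(x) == 18, length(bundle) == 18, all(bundle %in% 1:3))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance subtest: z-standardization undefined")
  z <- scale(x)
  data.frame(bis_capacity = rowMeans(z[, bundle == 1, drop = FALSE]),
             bis_speed    = rowMeans(z[, bundle == 2, drop = FALSE]),
             bis_memory   = rowMeans(z[, bundle == 3, drop = FALSE]))
}

#' One-pass outlier screen on poor-performance tails
#'
#' Removes subjects whose score on any screened variable exceeds the
#' pre-filter sample mean by more than `sd_limit` standard deviations
#' (one-sided, high = poor, by default; a two-sided option also removes
#' low extremes). Applied once, without re-iteration.
#'
#' @param measures data frame of subject measures (see
#'   [simulate_measures()]).
#' @param vars variables to screen; default: the four timing scores and
#'   the smallest-size motion threshold.
#' @param sd_limit SD multiple (default 3).
#' @param two_sided also remove low extremes.
#' @return list with `data` (filtered), `removed` (rows removed), and a
#'   `log` data frame of removal reasons.
#' @export
outlier_filter <- function(measures,
                           vars = c("dl_empty", "dl_filled", "tg_inverted",
                                    "rp_threshold", "mdd_1"),
                           sd_limit = 3, two_sided = FALSE) {
  stopifnot(all(vars %in% names(measures)))
  if (nrow(measures) < 3) {
    warning("fewer than 3 subjects: outlier filter skipped")
    return(list(data = measures, removed = measures[0, ], log = data.frame()))
  }
  bad <- rep(FALSE, nrow(measures))
  log <- data.frame()
  for (v in vars) {
    x <- measures[[v]]
    m <- mean(x); s <- stats::sd(x)
    hit <- x > m + sd_limit * s
    if (two_sided) hit <- hit | x < m - sd_limit * s
    if (any(hit))
      log <- rbind(log, data.frame(subject = measures$subject[hit],
                                   variable = v, value = x[hit],
                                   mean = m, sd = s))
    bad <- bad | hit
  }
  list(data = measures[!bad, , drop = FALSE],
       removed = measures[bad, , drop = FALSE], log = log)
}

#' Simulate the complete task battery for a population
#'
#' Produces one row of subject measures per observer. In `"trial"` mode
#' every task is run through its adaptive procedure at full length
#' (QUEST runs, staircases, generalization blocks); in `"measure"` mode
#' the measures are the observer's generative task parameters themselves
#' (log10 thresholds, discrimination/rhythm scales, generalization
#' spread), i.e. measurement without trial-sampling noise, which is the
#' mode used for parameter-recovery experiments. Intelligence composites
#' are scored from the simulated subtests in both modes.
#'
#' @param population a [sample_population()] result.
#' @param mode `"trial"` or `"measure"`.
#' @param seed integer seed for the trial-level randomness (defaults to
#'   the population seed + 1).
#' @return data frame of class `subject_measures` with columns `subject`,
#'   `mdd_1..mdd_4` (log10 ms), `si`, `dl_empty`, `dl_filled`,
#'   `tg_index_raw`, `tg_inverted`, `rp_threshold`, `bis_capacity`,
#'   `bis_speed`, `bis_memory`.
#' @export
simulate_measures <- function(population, mode = c("trial", "measure"),
                              seed = NULL) {
  stopifnot(inherits(population, "population"))
  mode <- match.arg(mode)
  obs <- population$observers
  n <- nrow(obs)
  bis <- score_bis(population$bis_subtests)

  if (mode == "measure") {
    out <- data.frame(
      subject = obs$subject,
      mdd_1 = obs$mdd_log_threshold_1, mdd_2 = obs$mdd_log_threshold_2,
      mdd_3 = obs$mdd_log_threshold_3, mdd_4 = obs$mdd_log_threshold_4,
      si = obs$mdd_log_threshold_4 - obs$mdd_log_threshold_1,
      dl_empty = obs$dd_jnd_empty, dl_filled = obs$dd_jnd_filled,
      tg_index_raw = tg_expected_index(obs$tg_sd,
                                       lapse = obs$lapse_rate[1]),
      rp_threshold = obs$rp_jnd)
    out$tg_inverted <- 1 - out$tg_index_raw
  } else {
    set.seed(seed %||% (population$spec$seed + 1L))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      o <- obs[i, ]
      ss <- run_spatial_suppression(o)
      dde <- run_duration_discrimination(o, "empty")
      ddf <- run_duration_discrimination(o, "filled")
      tg <- run_temporal_generalization(o)
      rp <- run_rhythm_perception(o)
      rows[[i]] <- data.frame(
        subject = o$subject,
        mdd_1 = ss$thresholds[1], mdd_2 = ss$thresholds[2],
        mdd_3 = ss$thresholds[3], mdd_4 = ss$thresholds[4],
        si = ss$si, dl_empty = dde$dl, dl_filled = ddf$dl,
        tg_index_raw = tg$index, rp_threshold = rp$threshold)
    }
    out <- do.call(rbind, rows)
    out$tg_inverted <- 1 - out$tg_index_raw
  }
  out <- cbind(out[c("subject", "mdd_1", "mdd_2", "mdd_3", "mdd_4", "si",
                     "dl_empty", "dl_filled", "tg_index_raw", "tg_inverted",
                     "rp_threshold")], bis)
  class(out) <- c("subject_measures", "data.frame")
  out
}
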
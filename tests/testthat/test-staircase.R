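test_that("an all-correct sequence walks down to the floor", {
  st <- staircase_init(20, series_length = 32)
  for (i in 1:32) st <- staircase_next(st, TRUE)
  expect_true(all(diff(st$levels) <= 0))
  expect_equal(min(st$levels), st$floor)
})

test_that("step sizes switch by the index of the trial just answered", {
  st <- staircase_init(30, series_length = 32)
  for (i in 1:5) st <- staircase_next(st, TRUE)   # trials 1-5: step 3 down
  expect_equal(st$levels, c(30, 27, 24, 21, 18, 15))
  st <- staircase_next(st, FALSE)                 # trial 6 still uses 9 up
  expect_equal(st$levels[7], 15 + 9)
  st <- staircase_next(st, FALSE)                 # trial 7 uses the 6/2 pair
  expect_equal(st$levels[8], 24 + 6)
  st <- staircase_next(st, TRUE)
  expect_equal(st$levels[9], 30 - 2)
})

test_that("equilibrium percent correct follows the step ratio", {
  expect_equal(staircase_equilibrium_p(9, 3), 0.75)
  expect_equal(staircase_equilibrium_p(6, 2), 0.75)
  expect_equal(staircase_equilibrium_p(12, 4), 0.75)
  expect_equal(staircase_equilibrium_p(3, 1), 0.75)
  expect_equal(staircase_equilibrium_p(1, 1), 0.5)
})

test_that("the threshold is the mean level of the last twenty trials", {
  st <- staircase_init(10, steps = list(c(up = 1, down = 1)),
                       series_length = 32)
  for (i in 1:32) st <- staircase_next(st, FALSE)
  # levels 10, 11, ..., 41; last 20 presented: 22..41
  expect_equal(staircase_threshold(st), mean(22:41))
  st2 <- staircase_init(5, series_length = 32)
  expect_error(staircase_threshold(st2), "incomplete")
})

test_that("long-run observed percent correct matches the step-ratio equilibrium", {
  for (steps in list(c(9, 3), c(6, 2), c(12, 4))) {
    set.seed(sum(steps))
    st <- staircase_init(60, steps = list(steps), series_length = 4000,
                         floor = 0.01)
    run <- staircase_run(function(d) runif(1) < pf_logistic_delta(d, 30),
                         st, 4000)
    frac <- mean(run$trials$correct[501:4000])
    expect_equal(frac, 0.75, tolerance = 0.02)
  }
})

test_that("interleaving balances series and preserves their internal order", {
  set.seed(4)
  sched <- interleave_series(32, 32)
  expect_equal(nrow(sched), 64)
  expect_equal(sum(sched$series == 1), 32)
  expect_equal(sum(sched$series == 2), 32)
  expect_equal(sched$within_trial[sched$series == 1], 1:32)
  expect_equal(sched$within_trial[sched$series == 2], 1:32)
  expect_equal(sum(sched$standard_first[sched$series == 1]), 16)
  expect_equal(sum(sched$standard_first[sched$series == 2]), 16)
  # reproducible under a seed
  set.seed(4); a <- interleave_series(32, 32)
  set.seed(4); b <- interleave_series(32, 32)
  expect_identical(a, b)
  expect_error(interleave_series(10, 12), "equal")
  # one warning per series with an odd count
  expect_warning(expect_warning(interleave_series(3, 3), "odd"), "odd")
})
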
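test_that("events are recovered from the CoP butterfly to within a sample", {
  cfg <- gait_config(n_strides = 60)
  tr <- simulate_trial(cfg, seed = 14)
  det <- detect_events_from_cop(tr$signals$cop_ap_m, tr$signals$cop_ml_m,
                                tr$fs)
  rate <- trial_match_rate(tr$truth$events, det, tol = 1,
                           skip_boundary = 2L)
  expect_gte(rate, 0.99)
})

test_that("degenerate CoP input fails explicitly rather than silently", {
  expect_error(detect_events_from_cop(rep(0, 2000), rep(0.03, 2000), 200),
               "no gait events")
  expect_error(detect_events_from_cop(rnorm(2000, sd = 1e-4),
                                      rnorm(2000, sd = 1e-4), 200),
               "no gait events|fewer than 3")
})

test_that("time reversal swaps heel-strike and toe-off roles", {
  cfg <- gait_config(n_strides = 40)
  tr <- simulate_trial(cfg, seed = 15)
  n <- nrow(tr$signals)
  det_rev <- detect_events_from_cop(rev(tr$signals$cop_ap_m),
                                    rev(tr$signals$cop_ml_m), tr$fs)
  # a reversed-time heel strike is the completion of a transfer in original
  # time, i.e. a toe-off
  hs_rev <- sort(n + 1L - unlist(det_rev$heel_strikes))
  to_true <- sort(unlist(tr$truth$events$toe_offs))
  matched <- vapply(hs_rev, function(x) any(abs(to_true - x) <= 2),
                    logical(1))
  expect_gte(mean(matched), 0.97)
})

test_that("segmentation yields one window per step with positive phases", {
  cfg <- gait_config(n_strides = 50)
  tr <- simulate_trial(cfg, seed = 16)
  steps <- segment_steps(tr$truth$events)
  expect_equal(nrow(steps), 2 * 50)  # truth events lose no boundary steps
  expect_true(all(steps$ds_duration > 0))
  expect_true(all(steps$ss_duration > 0))
  expect_true(all(steps$side != steps$trailing_side))
  # interleaving: sides alternate along the trial
  expect_true(all(steps$side[-1] != steps$side[-nrow(steps)]))
})

test_that("a deleted toe-off drops exactly one step, with a warning", {
  cfg <- gait_config(n_strides = 30)
  tr <- simulate_trial(cfg, seed = 17)
  ev <- tr$truth$events
  n_full <- nrow(segment_steps(ev))
  ev2 <- ev
  ev2$toe_offs$left <- ev2$toe_offs$left[-5]
  expect_warning(steps2 <- segment_steps(ev2), "dropped 1 step")
  expect_equal(nrow(steps2), n_full - 1L)
})

test_that("a single heel-strike pair with one toe-off gives one step", {
  ev <- new_gait_events(hs_left = 100, hs_right = 220,
                        to_left = 500, to_right = 124, fs = 200)
  steps <- segment_steps(ev)
  expect_equal(nrow(steps), 1L)
  expect_gt(steps$ds_duration, 0)
  expect_gt(steps$ss_duration, 0)
  expect_equal(steps$side, "left")
  expect_equal(steps$trailing_side, "right")
})

test_that("normalization is exact on constants and ramps", {
  fs <- 200
  tt <- (0:999) / fs
  sig <- data.frame(time_s = tt, const = rep(3.5, 1000), ramp = 2 * tt - 1)
  ev <- new_gait_events(hs_left = c(101, 501), hs_right = 301,
                        to_left = 361, to_right = 161, fs = fs)
  steps <- segment_steps(ev)
  sm <- time_normalize(sig, steps, J_ds = 10, J_ss = 30)
  expect_true(all(sm$channels$const == 3.5))
  # linear interpolation reproduces the ramp exactly at the grid times
  for (i in seq_len(nrow(steps))) {
    tg <- c(tt[steps$hs[i]] +
              (tt[steps$to[i]] - tt[steps$hs[i]]) * (0:9) / 10,
            tt[steps$to[i]] +
              (tt[steps$next_hs[i]] - tt[steps$to[i]]) * (0:29) / 29)
    expect_equal(sm$channels$ramp[i, ], 2 * tg - 1, tolerance = 1e-12)
  }
})

test_that("normalization error on band-limited signals is bounded", {
  fs <- 200
  tt <- (0:999) / fs
  f0 <- 4  # Hz
  sig <- data.frame(time_s = tt, s = sin(2 * pi * f0 * tt))
  ev <- new_gait_events(hs_left = c(101, 501), hs_right = 301,
                        to_left = 361, to_right = 161, fs = fs)
  steps <- segment_steps(ev)
  sm <- time_normalize(sig, steps, J_ds = 10, J_ss = 30)
  # dense-grid oracle: the true signal at the grid times; linear
  # interpolation error <= h^2/8 * max|f''|
  bound <- (1 / fs)^2 / 8 * (2 * pi * f0)^2
  for (i in seq_len(nrow(steps))) {
    tg <- c(tt[steps$hs[i]] +
              (tt[steps$to[i]] - tt[steps$hs[i]]) * (0:9) / 10,
            tt[steps$to[i]] +
              (tt[steps$next_hs[i]] - tt[steps$to[i]]) * (0:29) / 29)
    expect_lt(max(abs(sm$channels$s[i, ] - sin(2 * pi * f0 * tg))),
              1.01 * bound)
  }
})

test_that("normalization is idempotent on already-normalized rows", {
  # a signal sampled on the phase grid of a single step re-normalizes to
  # itself when the sub-window boundaries coincide
  fs <- 100
  J_ds <- 10; J_ss <- 40
  tt <- (0:(J_ds + J_ss - 1)) / fs
  set.seed(40)
  y <- cumsum(rnorm(J_ds + J_ss))
  sig <- data.frame(time_s = tt, y = y)
  ev <- new_gait_events(hs_left = 1, hs_right = J_ds + J_ss,
                        to_left = integer(0), to_right = J_ds + 1, fs = fs)
  steps <- segment_steps(ev)
  sm <- time_normalize(sig, steps, J_ds = J_ds, J_ss = J_ss)
  expect_equal(as.vector(sm$channels$y), y, tolerance = 1e-12)
})

test_that("too-short sub-windows are dropped with a warning", {
  fs <- 200
  tt <- (0:999) / fs
  sig <- data.frame(time_s = tt, y = rnorm(1000))
  ev <- new_gait_events(hs_left = c(101, 501), hs_right = 301,
                        to_left = 302, to_right = 161, fs = fs)
  steps <- segment_steps(ev)
  expect_warning(sm <- time_normalize(sig, steps, 10, 30), "shorter than")
  expect_equal(nrow(sm$meta), nrow(steps) - 1L)
})
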
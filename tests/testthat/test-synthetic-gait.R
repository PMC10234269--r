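test_that("belt speed follows the dimensionless-speed rule", {
  expect_equal(belt_speed(1.0, 0.4), 0.4 * sqrt(9.81), tolerance = 1e-12)
  expect_equal(belt_speed(1.0, 0.4), 1.2528, tolerance = 1e-4)
  expect_equal(belt_speed(0.81, 0.2), 0.5638, tolerance = 1e-4)
  expect_equal(belt_speed(0.9, 0), 0)
  expect_error(belt_speed(-1, 0.4), "positive")
  expect_error(belt_speed(1, -0.1), "non-negative")
})

test_that("configuration invariants are enforced", {
  expect_s3_class(gait_config(), "gait_config")
  expect_error(gait_config(n_strides = 2), "at least 3")
  expect_error(gait_config(ds_fraction = 0.6), "0, 0.5")
  expect_error(gait_config(sigma_fp = -1), "non-negative")
  expect_error(gait_config(step_time = 0.05), "20 samples")
  expect_error(gait_config(com_transition = diag(2) * 1.1),
               "spectral radius")
})

test_that("simulation is bit-identical given config and seed", {
  cfg <- small_config()
  t1 <- simulate_trial(cfg, seed = 4)
  t2 <- simulate_trial(cfg, seed = 4)
  expect_identical(t1$signals, t2$signals)
  expect_identical(t1$truth$fp_errors, t2$truth$fp_errors)
  t3 <- simulate_trial(cfg, seed = 5)
  expect_false(identical(t1$signals$cop_ml_m, t3$signals$cop_ml_m))
  s1 <- simulate_step_data(cfg, seed = 4)
  s2 <- simulate_step_data(cfg, seed = 4)
  expect_identical(s1$channels, s2$channels)
})

test_that("combined GRF is the sum of the per-leg forces at every sample", {
  tr <- simulate_trial(small_config(), seed = 2)
  expect_equal(tr$signals$grf_ap_combined_N,
               tr$signals$grf_ap_left_N + tr$signals$grf_ap_right_N,
               tolerance = 1e-12)
})

test_that("per-leg kinetics are exactly zero during that leg's swing", {
  tr <- simulate_trial(small_config(), seed = 3)
  ev <- tr$truth$events
  s <- tr$signals
  for (sd in c("left", "right")) {
    # swing: from each toe-off to that side's next heel strike
    for (to in ev$toe_offs[[sd]]) {
      nxt <- ev$heel_strikes[[sd]][ev$heel_strikes[[sd]] > to]
      if (!length(nxt)) next
      win <- (to):(nxt[1] - 1L)
      grf <- s[[paste0("grf_ap_", sd, "_N")]][win]
      mom <- s[[paste0("ankle_moment_", sd, "_Nm")]][win]
      expect_identical(max(abs(grf)), 0)
      expect_identical(max(abs(mom)), 0)
    }
  }
})

test_that("ground-truth errors are Gaussian with the configured scale", {
  cfg <- gait_config(n_strides = 5000)
  sdd <- simulate_step_data(cfg, seed = 8)
  expect_lt(abs(mean(sdd$errors)), 3 * cfg$sigma_fp / sqrt(sdd$n_steps))
  expect_equal(sd(sdd$errors), cfg$sigma_fp, tolerance = 0.03)
  expect_gt(shapiro.test(sdd$errors[1:5000])$p.value, 1e-4)
})

test_that("expected correlation profile matches the analytic form", {
  cfg <- gait_config()
  # zero gain -> identically zero
  p0 <- expected_correlation_profile(gait_config(gain_grf = 0),
                                     "trailing_ap_grf")
  expect_true(all(p0$r[!p0$masked] == 0))
  # noiseless limit with a strictly positive gain -> 1 over double stance
  p1 <- expected_correlation_profile(
    gait_config(sigma_eta_grf = 0, gain_shape = "flat"),
    "trailing_ap_grf", scope = "next_step")
  expect_true(all(p1$r[seq_len(cfg$J_ds)] == 1))
  # a gain profile that touches zero while the noise is zero is degenerate
  expect_error(expected_correlation_profile(
    gait_config(sigma_eta_grf = 0), "trailing_ap_grf"),
    "degenerate|undefined")
  # direct arithmetic: gain 2, sigma_fp 1, sigma_eta 2 -> 2 / sqrt(8)
  pc <- expected_correlation_profile(
    gait_config(gain_grf = 2, sigma_fp = 1, sigma_eta_grf = 2,
                gain_shape = "flat"),
    "trailing_ap_grf", scope = "next_step")
  expect_equal(unique(pc$r[seq_len(cfg$J_ds)]), 2 / sqrt(8),
               tolerance = 1e-12)
  expect_equal(2 / sqrt(8), 0.7071, tolerance = 1e-4)
  # degenerate variance is an explicit error, not NaN
  expect_error(expected_correlation_profile(
    gait_config(sigma_fp = 0), "trailing_ap_grf"), "degenerate|undefined")
})

test_that("unit-gain construction converges to r = 1/sqrt(2)", {
  ucfg <- gait_config(n_strides = 10000, gain_grf = 1, sigma_fp = 1,
                      sigma_eta_grf = 1, gain_shape = "flat")
  sdd <- simulate_step_data(ucfg, seed = 21)
  f <- pushoff_correlation_field(sdd$errors, sdd$channels,
                                 "trailing_ap_grf", J_ds = ucfg$J_ds)
  J <- ucfg$J_ds + ucfg$J_ss
  ds_cols <- J + seq_len(ucfg$J_ds)
  expect_equal(mean(f$r[ds_cols]), 1 / sqrt(2), tolerance = 0.01)
})

test_that("zero error variance propagates as an explicit degenerate case", {
  cfg <- small_config(sigma_fp = 0)
  sdd <- simulate_step_data(cfg, seed = 6)
  expect_true(all(sdd$errors == 0))
  expect_error(
    pushoff_correlation_field(sdd$errors, sdd$channels, "trailing_ap_grf",
                              J_ds = cfg$J_ds),
    "zero variance")
})

test_that("true state matrices give an exactly solvable regression", {
  cfg <- gait_config()
  set.seed(31)
  p <- rnorm(40, cfg$com_state_mean[1], 0.01)
  v <- rnorm(40, cfg$com_state_mean[2], 0.04)
  tm <- true_state_matrices(p, v, cfg)
  fp <- cfg$beta_pos * p + cfg$beta_vel * v
  fit <- fit_fpm(fp - mean(fp), tm$com_pos, tm$com_vel)
  tc <- fpm_true_coefficients(cfg)
  expect_lt(max(abs(fit$beta_pos - tc$beta_pos)), 1e-10)
  expect_lt(max(abs(fit$beta_vel - tc$beta_vel)), 1e-10)
  expect_lt(max(abs(fit$r_squared - 1)), 1e-10)
  # the map reduces to the identity at the closing heel strike
  J <- cfg$J_ds + cfg$J_ss
  expect_equal(tm$com_pos[, J], p)
  expect_equal(tm$com_vel[, J], v)
})

test_that("estimated correlation fields converge to the analytic profile", {
  devs <- sapply(c(200, 2000), function(n) {
    cfg <- gait_config(n_strides = n)
    sdd <- simulate_step_data(cfg, seed = 90 + n)
    f <- pushoff_correlation_field(sdd$errors, sdd$channels,
                                   "trailing_ankle_moment", J_ds = cfg$J_ds)
    ex <- expected_correlation_profile(cfg, "trailing_ankle_moment",
                                       scope = "full_stride")
    ok <- !ex$masked
    max(abs(f$r[ok] - ex$r[ok]))
  })
  # sup-norm deviation shrinks roughly as 1/sqrt(n)
  expect_lt(devs[2], devs[1])
  expect_lt(devs[1], 6 / sqrt(2 * 200))
  expect_lt(devs[2], 6 / sqrt(2 * 2000))
})
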
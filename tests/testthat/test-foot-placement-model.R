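test_that("CoM states are stance-referenced and translation invariant", {
  set.seed(50)
  pos <- matrix(rnorm(60), 6, 10)
  vel <- matrix(rnorm(60), 6, 10)
  ref <- rnorm(6)
  st <- compute_com_states(pos, vel, ref)
  expect_equal(st$com_pos, pos - ref)
  expect_equal(st$com_vel, vel)
  # CoM coincident with the stance foot -> zero everywhere
  st0 <- compute_com_states(matrix(ref, 6, 10), vel, ref)
  expect_true(all(st0$com_pos == 0))
  # shifting the whole trial leaves relative coordinates unchanged
  st_shift <- compute_com_states(pos + 0.5, vel, ref + 0.5)
  expect_equal(st_shift$com_pos, st$com_pos)
  # missing reference drops the step with a warning
  ref[3] <- NA
  expect_warning(st2 <- compute_com_states(pos, vel, ref), "reference")
  expect_equal(st2$steps, c(1, 2, 4, 5, 6))
})

test_that("foot placement is the de-meaned trailing-to-leading distance", {
  fp <- compute_foot_placement(c(0.50, 0.60, 0.70), c(0, 0, 0))
  expect_equal(as.numeric(fp), c(-0.10, 0, 0.10))
  expect_equal(attr(fp, "mean"), 0.60)
  expect_error(compute_foot_placement(c(1, 2), c(0, 0)), "at least 3")
  # identical steps -> identically zero
  expect_true(all(compute_foot_placement(rep(0.7, 5), rep(0, 5)) == 0))
})

test_that("the phase-wise fit matches the normal-equations oracle", {
  # worked 3-step example with collinearity broken in one entry
  fp <- c(-0.10, 0, 0.10)
  pos <- c(-0.02, 0.003, 0.02)
  vel <- c(-0.05, 0, 0.05)
  fit <- fit_fpm(fp, matrix(pos, 3, 2), matrix(vel, 3, 2))
  beta <- ols2_oracle(fp - mean(fp), pos - mean(pos), vel - mean(vel))
  expect_equal(fit$beta_pos, rep(beta[1], 2), tolerance = 1e-12)
  expect_equal(fit$beta_vel, rep(beta[2], 2), tolerance = 1e-12)

  # larger random case, every phase against the oracle
  set.seed(51)
  n <- 25; J <- 7
  P <- matrix(rnorm(n * J), n, J)
  V <- matrix(rnorm(n * J), n, J)
  y <- rnorm(n)
  fit2 <- fit_fpm(y, P, V)
  for (j in seq_len(J)) {
    b <- ols2_oracle(y - mean(y), P[, j] - mean(P[, j]),
                     V[, j] - mean(V[, j]))
    expect_equal(c(fit2$beta_pos[j], fit2$beta_vel[j]), unname(b),
                 tolerance = 1e-10)
  }
})

test_that("residual means vanish and errors average to zero exactly", {
  set.seed(52)
  n <- 40; J <- 12
  fit <- fit_fpm(rnorm(n), matrix(rnorm(n * J), n, J),
                 matrix(rnorm(n * J), n, J))
  expect_lt(max(abs(colMeans(fit$residuals))), 1e-10)
  expect_lt(abs(mean(foot_placement_errors(fit))), 1e-12)
})

test_that("R^2 is scale invariant while coefficients scale inversely", {
  set.seed(53)
  n <- 30; J <- 5
  P <- matrix(rnorm(n * J), n, J); V <- matrix(rnorm(n * J), n, J)
  y <- rnorm(n)
  f1 <- fit_fpm(y, P, V)
  f2 <- fit_fpm(y, 10 * P, 0.5 * V)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
  expect_equal(f2$beta_pos, f1$beta_pos / 10, tolerance = 1e-12)
  expect_equal(f2$beta_vel, f1$beta_vel / 0.5, tolerance = 1e-12)
})

test_that("null R^2 has expectation 2/(n-1)", {
  set.seed(54)
  n <- 20
  r2 <- replicate(3000, {
    fit_fpm(rnorm(n), matrix(rnorm(n), n, 1),
            matrix(rnorm(n), n, 1))$r_squared
  })
  expect_lt(abs(mean(r2) - 2 / (n - 1)), 0.012)
})

test_that("rank-deficient phases are flagged, not silently zeroed", {
  set.seed(55)
  n <- 10
  x <- rnorm(n)
  fit <- fit_fpm(rnorm(n), cbind(x, x), cbind(2 * x, rnorm(n)))
  expect_true(fit$flagged[1])
  expect_false(fit$flagged[2])
  expect_true(is.na(fit$beta_pos[1]))
})

test_that("a perfect fit yields zero errors", {
  set.seed(56)
  n <- 15
  p <- rnorm(n); v <- rnorm(n)
  y <- 0.4 * p + 0.2 * v
  fit <- fit_fpm(y - mean(y), matrix(p, n, 3), matrix(v, n, 3))
  expect_lt(max(abs(fit$r_squared - 1)), 1e-12)
  expect_lt(max(abs(foot_placement_errors(fit))), 1e-12)
})

test_that("error summaries estimate the Gaussian scale consistently", {
  set.seed(57)
  s <- summarize_errors(rnorm(20000, sd = 0.012))
  expect_equal(s$sd, 0.012, tolerance = 0.01)
  expect_equal(unname(s$mle["sd"]), s$sd, tolerance = 1e-4)
  expect_false(s$degenerate)
  expect_gt(s$normality$p_value, 1e-4)
  sc <- summarize_errors(rep(0.3, 10))
  expect_true(sc$degenerate)
  expect_identical(sc$sd, 0)
  expect_error(summarize_errors(c(1, 2)), "at least 3")
})

test_that("slow walking produces larger foot placement error spread", {
  e_norm <- simulate_step_data(gait_config("normal", n_strides = 400),
                               seed = 58)$errors
  e_slow <- simulate_step_data(gait_config("slow", n_strides = 400),
                               seed = 58)$errors
  expect_gt(summarize_errors(e_slow)$sd, summarize_errors(e_norm)$sd)
})

test_that("pipeline-estimated errors track ground truth on a full trial", {
  cfg <- gait_config(n_strides = 150)
  tr <- simulate_trial(cfg, seed = 59)
  steps <- segment_steps(tr$truth$events)
  sm <- time_normalize(tr$signals, steps, cfg$J_ds, cfg$J_ss)
  fpm <- fit_fpm_by_side(sm)
  # map stride-matrix rows back to generator step indices
  k <- round((sm$meta$hs - 1) / tr$truth$sps) + 1
  ok <- is.finite(fpm$errors)
  expect_gte(cor(fpm$errors[ok], tr$truth$fp_errors[k[ok]]), 0.95)
  # recovered heel-strike CoM states match stored truth
  st <- fit_fpm_by_side(sm)  # per-side fit already used the states; redo raw
  cs <- compute_com_states(sm$channels$com_pos_ap_m,
                           sm$channels$com_vel_ap_mps,
                           gaitfpe:::stance_reference(sm))
  J <- cfg$J_ds + cfg$J_ss
  expect_equal(cs$com_pos[, J], tr$truth$states$p_raw[k[cs$steps]],
               tolerance = 1e-8)
  expect_equal(cs$com_vel[, J], tr$truth$states$v_raw[k[cs$steps]],
               tolerance = 1e-8)
})
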
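# Synthetic treadmill gait generator.
#
# The generator mirrors the statistical structure the downstream analysis
# assumes: anterior-posterior (AP) foot placement is linear in the
# center-of-mass (CoM) state at heel strike with Gaussian residuals ("foot
# placement errors"), and the push-off kinetics of the *following* step covary
# with the preceding step's error through a tunable phase-dependent gain.
# All ground truth (events, CoM states, errors, gains) is retained so every
# pipeline stage can be validated without any recorded data.

#' Treadmill belt speed from leg length
#'
#' Belt speed is set as a fixed multiple of `sqrt(g * l)` with
#' `g = 9.81` m/s^2, i.e. at a constant dimensionless (Froude-consistent)
#' speed: coefficient 0.4 for normal and 0.2 for slow walking.
#'
#' @param leg_length leg length in meters (> 0).
#' @param speed_coefficient dimensionless speed coefficient (>= 0).
#' @return belt speed in m/s.
#' @examples
#' belt_speed(1.0, 0.4)
#' @export
belt_speed <- function(leg_length, speed_coefficient) {
  if (!is.numeric(leg_length) || any(leg_length <= 0)) {
    stop("`leg_length` must be positive", call. = FALSE)
  }
  if (!is.numeric(speed_coefficient) || any(speed_coefficient < 0)) {
    stop("`speed_coefficient` must be non-negative", call. = FALSE)
  }
  speed_coefficient * sqrt(9.81 * leg_length)
}

#' Configuration for the synthetic gait generator
#'
#' Returns a validated configuration object. Condition-dependent defaults
#' emulate steady-state treadmill walking at a normal or slow belt speed:
#' the slow condition walks at half the dimensionless speed, with a longer
#' step time, a longer relative double stance, a larger foot-placement error
#' SD and weaker kinetic feedback gains.
#'
#' @param condition `"normal"` or `"slow"`.
#' @param n_strides number of strides (two steps each); default 200.
#' @param fs sampling rate in Hz.
#' @param leg_length leg length in meters.
#' @param step_time step duration in seconds (heel strike to contralateral
#'   heel strike).
#' @param ds_fraction fraction of the step spent in double stance (0-0.5).
#' @param speed_coefficient dimensionless belt-speed coefficient.
#' @param beta_pos,beta_vel generating regression coefficients of AP foot
#'   placement on the CoM AP position (dimensionless) and velocity (s) at
#'   heel strike.
#' @param sigma_fp SD of the foot placement error in meters.
#' @param com_transition 2x2 step-to-step transition matrix of the heel-strike
#'   CoM state deviations (position, velocity); spectral radius must be < 1.
#' @param com_noise_sd innovation SDs (m, m/s) of the step-to-step state map.
#' @param com_state_mean mean heel-strike CoM state (m, m/s) relative to the
#'   per-step stance-foot reference; velocity is in the lab (treadmill) frame.
#' @param grf_amp amplitude of the baseline AP ground reaction force profile
#'   per leg (N): braking lobe followed by a propulsive lobe.
#' @param moment_peak peak of the baseline plantar-flexion ankle moment
#'   profile (N m).
#' @param gain_grf,gain_moment peak feedback gains from the preceding foot
#'   placement error to the trailing leg's AP GRF (N/m) and ankle moment
#'   (N m / m) over its final double stance.
#' @param gain_shape shape of the gain profile over the double stance:
#'   `"skewed_hann"` (smooth, zero at both ends, peak about two thirds in) or
#'   `"flat"` (constant, strictly positive over the whole double stance).
#' @param sigma_eta_grf,sigma_eta_moment pointwise SD of the smooth kinetic
#'   noise per leg (N, N m).
#' @param noise_fwhm smoothness of within-step noise, as full width at half
#'   maximum in percent of a step.
#' @param sigma_cop SD of the smooth noise added to the center-of-pressure
#'   channels (m).
#' @param step_width mediolateral distance between the feet (m), i.e. the
#'   peak-to-peak amplitude of the center-of-pressure "butterfly".
#' @param cop_excursion forward travel of the center of pressure under a foot
#'   over its stance (m).
#' @param J_ds,J_ss default phase-grid sizes (double-/single-stance samples)
#'   used by the step-level generator and the normalization defaults.
#' @param seed default RNG seed used by the simulators.
#' @return an object of class `gait_config` (a validated named list).
#' @seealso [simulate_trial()], [simulate_step_data()]
#' @export
gait_config <- function(condition = c("normal", "slow"),
                        n_strides = 200,
                        fs = 200,
                        leg_length = 0.9,
                        step_time = NULL,
                        ds_fraction = NULL,
                        speed_coefficient = NULL,
                        beta_pos = 0.6,
                        beta_vel = 0.25,
                        sigma_fp = NULL,
                        com_transition = matrix(c(0.3, 0.1, 0.05, 0.2), 2, 2),
                        com_noise_sd = c(0.01, 0.04),
                        com_state_mean = NULL,
                        grf_amp = 140,
                        moment_peak = 100,
                        gain_grf = NULL,
                        gain_moment = NULL,
                        gain_shape = c("skewed_hann", "flat"),
                        sigma_eta_grf = 7,
                        sigma_eta_moment = 4,
                        noise_fwhm = 10,
                        sigma_cop = 0.002,
                        step_width = 0.10,
                        cop_excursion = 0.18,
                        J_ds = NULL,
                        J_ss = NULL,
                        seed = 1L) {
  condition <- match.arg(condition)
  gain_shape <- match.arg(gain_shape)
  defaults <- switch(condition,
    normal = list(step_time = 0.60, ds_fraction = 0.20, speed_coefficient = 0.4,
                  sigma_fp = 0.008, gain_grf = 450, gain_moment = 220,
                  J_ds = 20L, J_ss = 80L),
    slow   = list(step_time = 0.75, ds_fraction = 0.25, speed_coefficient = 0.2,
                  sigma_fp = 0.011, gain_grf = 290, gain_moment = 150,
                  J_ds = 25L, J_ss = 75L)
  )
  pick <- function(x, d) if (is.null(x)) d else x
  cfg <- list(
    condition = condition,
    n_strides = as.integer(n_strides),
    fs = fs,
    leg_length = leg_length,
    step_time = pick(step_time, defaults$step_time),
    ds_fraction = pick(ds_fraction, defaults$ds_fraction),
    speed_coefficient = pick(speed_coefficient, defaults$speed_coefficient),
    beta_pos = beta_pos,
    beta_vel = beta_vel,
    sigma_fp = pick(sigma_fp, defaults$sigma_fp),
    com_transition = com_transition,
    com_noise_sd = com_noise_sd,
    com_state_mean = com_state_mean,  # filled below
    grf_amp = grf_amp,
    moment_peak = moment_peak,
    gain_grf = pick(gain_grf, defaults$gain_grf),
    gain_moment = pick(gain_moment, defaults$gain_moment),
    gain_shape = gain_shape,
    sigma_eta_grf = sigma_eta_grf,
    sigma_eta_moment = sigma_eta_moment,
    noise_fwhm = noise_fwhm,
    sigma_cop = sigma_cop,
    step_width = step_width,
    cop_excursion = cop_excursion,
    J_ds = as.integer(pick(J_ds, defaults$J_ds)),
    J_ss = as.integer(pick(J_ss, defaults$J_ss)),
    seed = as.integer(seed)
  )
  v <- belt_speed(cfg$leg_length, cfg$speed_coefficient)
  if (is.null(cfg$com_state_mean)) {
    # CoM roughly half a step length ahead of the per-step stance reference at
    # heel strike; mean CoM velocity ~ 0 in the lab frame on a treadmill.
    cfg$com_state_mean <- c(0.5 * v * cfg$step_time, 0)
  }
  cfg$belt_speed <- v
  class(cfg) <- "gait_config"
  validate_gait_config(cfg)
}

#' Validate a generator configuration
#'
#' @param config a `gait_config` object.
#' @return the configuration, invisibly unchanged, or an error.
#' @export
validate_gait_config <- function(config) {
  stopifnot(inherits(config, "gait_config"))
  with(config, {
    if (n_strides < 3) stop("`n_strides` must be at least 3", call. = FALSE)
    if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
    if (!(ds_fraction > 0 && ds_fraction < 0.5)) {
      stop("`ds_fraction` must lie in (0, 0.5)", call. = FALSE)
    }
    if (round(step_time * fs) < 20) {
      stop("step_time * fs must give at least 20 samples per step",
           call. = FALSE)
    }
    sds <- c(sigma_fp, com_noise_sd, sigma_eta_grf, sigma_eta_moment,
             sigma_cop)
    if (any(sds < 0)) stop("all SDs must be non-negative", call. = FALSE)
    if (!is.matrix(com_transition) || !all(dim(com_transition) == c(2, 2))) {
      stop("`com_transition` must be a 2x2 matrix", call. = FALSE)
    }
    if (spectral_radius(com_transition) >= 1) {
      stop("`com_transition` must have spectral radius < 1 (stationary ",
           "stepping)", call. = FALSE)
    }
    if (J_ds < 2 || J_ss < 2) stop("J_ds and J_ss must be >= 2", call. = FALSE)
  })
  invisible(config)
}

#' @export
print.gait_config <- function(x, ...) {
  cat("<gait_config>", x$condition, "walking:",
      x$n_strides, "strides @", x$fs, "Hz\n")
  cat("  belt speed", format(x$belt_speed, digits = 4), "m/s; step",
      x$step_time, "s; double stance", x$ds_fraction * 100, "% of step\n")
  cat("  beta_pos", x$beta_pos, " beta_vel", x$beta_vel, "s; sigma_fp",
      x$sigma_fp, "m\n")
  cat("  gains:", x$gain_grf, "N/m (AP GRF),", x$gain_moment,
      "N m/m (ankle moment), shape", x$gain_shape, "\n")
  invisible(x)
}

# Feedback gain over the trailing leg's final double stance, on tau in [0, 1).
gain_profile_eval <- function(tau, peak, shape) {
  switch(shape,
    skewed_hann = peak * sin(pi * tau^1.7095)^2,  # peak ~2/3 into the window
    flat = rep(peak, length(tau)),
    stop("unknown gain shape: ", shape, call. = FALSE)
  )
}

# Baseline AP GRF per leg over its stance (u in [0, 1]): braking lobe then a
# propulsive push-off lobe, zero at contact and toe-off.
stance_mu_grf <- function(u, amp) -amp * sin(2 * pi * u)

# Baseline internal plantar-flexion ankle moment over stance, peaking late
# (around push-off), zero at contact and toe-off.
stance_mu_moment <- function(u, peak) peak * (u^3 * (1 - u)) / (0.75^3 * 0.25)

# Fraction of the step time at each phase-grid column. The double stance is
# resampled to J_ds points over [0, ds) and the single stance to J_ss points
# over [ds, 1]; the last column is the contralateral heel strike (j = 100%).
step_grid_frac <- function(ds_fraction, J_ds, J_ss) {
  c(ds_fraction * (0:(J_ds - 1)) / J_ds,
    ds_fraction + (1 - ds_fraction) * (0:(J_ss - 1)) / (J_ss - 1))
}

# Analytic within-step propagation of the heel-strike CoM state. States at
# phase-time fraction s are a linear, invertible map of the state at the
# closing heel strike (s = 1):
#   vel(s) = v * omega(s),  pos(s) = p - T * v * g(s)
# with omega(1) = 1, g(1) = 0. Used for implied true coefficient curves and
# exact-recovery checks; the sampled signals use a C1 interpolation instead.
state_phase_map <- function(config, s) {
  a <- 0.2
  omega <- 1 - a * sin(pi * s)
  g <- (1 - s) - a * (1 + cos(pi * s)) / pi
  list(s = s, omega = omega, g = g, T = config$step_time)
}

#' True phase-dependent foot placement coefficients
#'
#' The generator draws foot placement from the CoM state at heel strike
#' (phase 100%). Because the within-step state propagation is a linear,
#' invertible map of that state, the regression of foot placement on the
#' states at any earlier phase has closed-form coefficients; this returns
#' those implied curves on the phase grid.
#'
#' @param config a [gait_config()].
#' @param J_ds,J_ss phase-grid sizes; default from `config`.
#' @return data.frame with columns `frac` (fraction of step time),
#'   `beta_pos`, `beta_vel`.
#' @export
fpm_true_coefficients <- function(config, J_ds = config$J_ds,
                                  J_ss = config$J_ss) {
  s <- step_grid_frac(config$ds_fraction, J_ds, J_ss) /
    1  # fractions already of step time
  m <- state_phase_map(config, s)
  data.frame(
    frac = s,
    beta_pos = rep(config$beta_pos, length(s)),
    beta_vel = (m$T * m$g * config$beta_pos + config$beta_vel) / m$omega
  )
}

#' Noise-free CoM state matrices on the phase grid
#'
#' Propagates per-step heel-strike CoM states backwards through the analytic
#' within-step map, giving steps x J matrices of CoM AP position and velocity
#' that are exactly linear in the heel-strike states. Together with
#' [fpm_true_coefficients()] these give an exactly solvable regression
#' problem: a foot placement vector built as
#' `beta_pos * p + beta_vel * v` is reproduced with zero residual at every
#' phase.
#'
#' @param p,v vectors of heel-strike CoM AP position (m) and velocity (m/s),
#'   one per step.
#' @param config a [gait_config()].
#' @param J_ds,J_ss phase-grid sizes.
#' @return list with matrices `com_pos`, `com_vel` (steps x (J_ds + J_ss)).
#' @export
true_state_matrices <- function(p, v, config, J_ds = config$J_ds,
                                J_ss = config$J_ss) {
  stopifnot(length(p) == length(v))
  s <- step_grid_frac(config$ds_fraction, J_ds, J_ss)
  m <- state_phase_map(config, s)
  list(
    com_pos = outer(p, rep(1, length(s))) - outer(v, m$T * m$g),
    com_vel = outer(v, m$omega)
  )
}

# Draw the step-to-step chain: closing CoM states and foot placement for
# steps 0..n_steps (step 0 is a pre-trial warm-up step whose error drives the
# first in-trial push-off). Assumes the RNG is already seeded.
simulate_step_core <- function(config, n_steps) {
  A <- config$com_transition
  Q <- diag(config$com_noise_sd^2)
  n <- n_steps + 1L  # steps 0..n_steps
  if (all(config$com_noise_sd == 0)) {
    x <- matrix(0, 2, n)
  } else {
    S <- stationary_cov(A, Q)
    x <- matrix(0, 2, n)
    x[, 1] <- t(chol(S + diag(1e-300, 2))) %*% stats::rnorm(2)
    innov <- rbind(stats::rnorm(n - 1, sd = config$com_noise_sd[1]),
                   stats::rnorm(n - 1, sd = config$com_noise_sd[2]))
    for (k in 2:n) x[, k] <- A %*% x[, k - 1] + innov[, k - 1]
  }
  eps <- stats::rnorm(n, sd = config$sigma_fp)
  fp_dev <- config$beta_pos * x[1, ] + config$beta_vel * x[2, ] + eps
  list(
    p_dev = x[1, ], v_dev = x[2, ],
    p_raw = config$com_state_mean[1] + x[1, ],
    v_raw = config$com_state_mean[2] + x[2, ],
    eps = eps,
    fp_dev = fp_dev,
    fp_raw = config$belt_speed * config$step_time + fp_dev
  )
}

# Per-stance kinetic matrix on a stance grid: row k (for the leg whose heel
# strike opened step k-1) is mu(u) + gain(tau) * eps_{k-1} + smooth noise,
# where the gain window is the leg's final double stance.
stance_kinetics_matrix <- function(eps, u, tau_idx, tau, mu, gain_peak,
                                   shape, sigma, fwhm_cols) {
  n <- length(eps)
  gain <- numeric(length(u))
  gain[tau_idx] <- gain_profile_eval(tau, gain_peak, shape)
  base <- matrix(mu, n, length(u), byrow = TRUE)
  base + outer(eps, gain) + smooth_noise(n, length(u), sigma, fwhm_cols)
}

#' Simulate step-level gait data on the phase grid
#'
#' Fast path of the generator: draws the step-to-step chain (CoM states, foot
#' placement, errors) and the per-step kinetic channels directly on the
#' normalized phase grid, bypassing continuous-signal synthesis and event
#' detection. Statistically identical in structure to the channels that
#' [simulate_trial()] plus the event/normalization pipeline produce; intended
#' for large-n convergence and calibration studies.
#'
#' @param config a [gait_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return an object of class `step_data`: a list with
#'   `errors` (ground-truth foot placement errors, steps 1..n),
#'   `fp_dev`, `fp_raw`, `states` (heel-strike CoM states),
#'   `channels` (per analysis signal, matrices on the step grid: for step i,
#'   `same_step` holds the reference leg's series during step i and
#'   `next_step` its series during step i+1, see [correlate_errors_kinetics()]),
#'   and grid metadata.
#' @export
simulate_step_data <- function(config, seed = config$seed) {
  validate_gait_config(config)
  with_seed(seed, {
    n_steps <- 2L * config$n_strides
    J_ds <- config$J_ds; J_ss <- config$J_ss
    J <- J_ds + J_ss
    ds <- config$ds_fraction
    core <- simulate_step_core(config, n_steps)

    # stance grid: the whole step (J columns) plus the final double stance of
    # the following step (J_ds columns); stance duration (1 + ds) steps.
    frac_step <- step_grid_frac(ds, J_ds, J_ss)
    frac_next <- 1 + ds * (0:(J_ds - 1)) / J_ds
    u <- c(frac_step, frac_next) / (1 + ds)
    tau_idx <- J + seq_len(J_ds)
    tau <- (0:(J_ds - 1)) / J_ds
    fwhm_cols <- config$noise_fwhm / 100 * J

    st_grf <- stance_kinetics_matrix(
      core$eps, u, tau_idx, tau, stance_mu_grf(u, config$grf_amp),
      config$gain_grf, config$gain_shape, config$sigma_eta_grf, fwhm_cols)
    st_mom <- stance_kinetics_matrix(
      core$eps, u, tau_idx, tau, stance_mu_moment(u, config$moment_peak),
      config$gain_moment, config$gain_shape, config$sigma_eta_moment,
      fwhm_cols)

    steps <- seq_len(n_steps)
    split_channels <- function(st) {
      # rows of `st` are stances opened at steps 0..n_steps (row k+1 <-> k)
      trailing <- cbind(st[steps, tau_idx, drop = FALSE],
                        matrix(0, n_steps, J_ss))
      stance_leg <- st[steps + 1L, seq_len(J), drop = FALSE]
      list(trailing = trailing, stance_leg = stance_leg,
           combined = stance_leg + trailing)
    }
    g <- split_channels(st_grf)
    m <- split_channels(st_mom)
    channels <- list(
      combined_ap_grf = list(same_step = g$combined, next_step = g$combined),
      trailing_ap_grf = list(same_step = g$stance_leg, next_step = g$trailing),
      trailing_ankle_moment = list(same_step = m$stance_leg,
                                   next_step = m$trailing)
    )
    structure(list(
      errors = core$eps[steps + 1L],
      fp_dev = core$fp_dev[steps + 1L],
      fp_raw = core$fp_raw[steps + 1L],
      states = data.frame(step = steps,
                          p_dev = core$p_dev[steps + 1L],
                          v_dev = core$v_dev[steps + 1L],
                          p_raw = core$p_raw[steps + 1L],
                          v_raw = core$v_raw[steps + 1L]),
      channels = channels,
      J_ds = J_ds, J_ss = J_ss, frac = frac_step,
      n_steps = n_steps, config = config, seed = seed
    ), class = "step_data")
  })
}

#' Expected error-kinetics correlation profile
#'
#' Closed-form target for the correlation fields estimated downstream. With a
#' feedback gain profile `g(j)`, foot placement error SD `sigma_fp` and
#' pointwise kinetic noise SD `sigma_eta`, the population correlation at
#' phase `j` is
#' `r*(j) = g(j) sigma_fp / sqrt(g(j)^2 sigma_fp^2 + sigma_eta^2)`.
#' For the combined AP GRF both legs contribute independent noise during the
#' double stance, so its noise variance is doubled there. Phases where a
#' per-leg signal is identically zero (the trailing leg's swing) are masked.
#'
#' @param config a [gait_config()].
#' @param signal one of `"combined_ap_grf"`, `"trailing_ap_grf"`,
#'   `"trailing_ankle_moment"`.
#' @param scope `"full_stride"` (default; step i then step i+1 relative to the
#'   error of step i) or `"next_step"`.
#' @param J_ds,J_ss phase-grid sizes.
#' @return data.frame with `phase` (percent of the stride or step), `r`
#'   (expected correlation) and `masked`.
#' @export
expected_correlation_profile <- function(config,
                                         signal = c("trailing_ap_grf",
                                                    "trailing_ankle_moment",
                                                    "combined_ap_grf"),
                                         scope = c("full_stride", "next_step"),
                                         J_ds = config$J_ds,
                                         J_ss = config$J_ss) {
  validate_gait_config(config)
  signal <- match.arg(signal)
  scope <- match.arg(scope)
  J <- J_ds + J_ss
  sigma_eta <- switch(signal,
    combined_ap_grf = config$sigma_eta_grf,
    trailing_ap_grf = config$sigma_eta_grf,
    trailing_ankle_moment = config$sigma_eta_moment)
  if (config$sigma_fp == 0) {
    stop("sigma_fp is zero: foot placement errors are degenerate and the ",
         "correlation profile is undefined", call. = FALSE)
  }
  tau <- (0:(J_ds - 1)) / J_ds
  g <- gain_profile_eval(tau, switch(signal,
    combined_ap_grf = config$gain_grf,
    trailing_ap_grf = config$gain_grf,
    trailing_ankle_moment = config$gain_moment), config$gain_shape)
  noise_var_ds <- if (signal == "combined_ap_grf") 2 * sigma_eta^2 else
    sigma_eta^2
  if (all(g == 0) && noise_var_ds == 0) {
    stop("gain and kinetic noise are both zero: correlation undefined",
         call. = FALSE)
  }
  denom <- sqrt(g^2 * config$sigma_fp^2 + noise_var_ds)
  if (any(denom == 0)) {
    stop("degenerate variance at some phases: correlation undefined",
         call. = FALSE)
  }
  r_ds <- g * config$sigma_fp / denom
  r_next <- c(r_ds, rep(0, J_ss))
  mask_next <- c(rep(FALSE, J_ds),
                 rep(signal != "combined_ap_grf", J_ss))
  if (scope == "next_step") {
    return(data.frame(phase = 100 * (seq_len(J) - 1) / (J - 1),
                      r = r_next, masked = mask_next))
  }
  r <- c(rep(0, J), r_next)
  masked <- c(rep(FALSE, J), mask_next)
  data.frame(phase = 100 * (seq_len(2 * J) - 1) / (J - 1) - 100,
             r = r, masked = masked)
}
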
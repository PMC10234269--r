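# Continuous-signal synthesis: turns the step-to-step chain into sampled
# multichannel gait signals with a detectable center-of-pressure butterfly.

# Smooth Gaussian noise for a long series; circular convolution keeps the
# pointwise SD exact at the edges.
smooth_noise_series <- function(n, sd, fwhm) {
  if (sd == 0) return(numeric(n))
  if (fwhm <= 0) return(stats::rnorm(n, sd = sd))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sqrt(sum(k^2))
  x <- stats::rnorm(n)
  as.numeric(stats::filter(x, k, sides = 2, circular = TRUE)) * sd
}

#' Simulate a synthetic treadmill walking trial
#'
#' Generates a full multichannel trial in the lab (treadmill) frame:
#' center-of-pressure (AP and mediolateral), per-leg and combined AP ground
#' reaction force, per-leg sagittal ankle moment, whole-body CoM AP position
#' and velocity, and per-foot heel AP position, together with a ground-truth
#' sidecar (gait events, heel-strike CoM states, foot placement and its
#' errors).
#'
#' Stride loop: heel-strike CoM states follow a stationary step-to-step
#' linear map; AP foot placement is linear in those states plus a Gaussian
#' error; within-step CoM trajectories are C1 cubic interpolations consistent
#' with the drawn heel-strike states; each leg's stance kinetics are a smooth
#' baseline profile plus smooth Gaussian noise plus, over its final double
#' stance, a gain profile times the preceding step's foot placement error;
#' the combined CoP alternates mediolaterally between the feet with a linear
#' transfer over each double stance (the "butterfly") and drifts backwards
#' under the stance foot at belt speed. Per-leg kinetics are exactly zero in
#' swing. Deterministic given the seed.
#'
#' @param config a [gait_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return an object of class `synthetic_trial`: list with `signals`
#'   (data.frame of sampled channels), `fs`, `condition`, and `truth`
#'   (list: `events` ([gait_events] object), `fp_errors`, `fp_dev`, `fp_raw`,
#'   `states`, `sps`, `dss`).
#' @examples
#' trial <- simulate_trial(gait_config(n_strides = 5), seed = 1)
#' str(trial$truth$fp_errors)
#' @export
simulate_trial <- function(config, seed = config$seed) {
  validate_gait_config(config)
  fs <- config$fs
  sps <- as.integer(round(config$step_time * fs))
  dss <- as.integer(round(config$ds_fraction * sps))
  if (dss < 2L) stop("double stance shorter than 2 samples", call. = FALSE)
  n_steps <- 2L * config$n_strides
  n_total <- n_steps * sps + 1L
  tvec <- (seq_len(n_total) - 1) / fs
  v_belt <- config$belt_speed
  Tstep <- sps / fs
  idx_hs <- function(k) (k - 1L) * sps + 1L     # k = 0..n_steps+1
  idx_to <- function(k) idx_hs(k) + dss
  side_of <- function(k) ifelse(k %% 2L == 1L, "left", "right")

  with_seed(seed, {
    core <- simulate_step_core(config, n_steps)
    # offset-indexed vectors: X[k + 1L] is the quantity of step k (k >= 0)
    at <- function(x, k) x[k + 1L]
    H <- cumsum(c(0, core$fp_dev))              # H[k+1] = strike pos, k=0..n+1
    G <- H[seq_len(n_steps + 1L)] + core$p_raw  # G[k] = CoM at HS_k, k=1..n+1

    # --- CoM trajectory: C1 cubic Hermite between heel-strike states -------
    com_pos <- numeric(n_total)
    com_vel <- numeric(n_total)
    s_in <- (0:(sps - 1L)) / sps
    for (k in seq_len(n_steps)) {
      i0 <- idx_hs(k)
      v0 <- at(core$v_raw, k - 1L)
      v1 <- at(core$v_raw, k)
      sel <- i0:(i0 + sps - 1L)
      com_pos[sel] <- hermite01(s_in, G[k], G[k + 1L], Tstep * v0, Tstep * v1)
      com_vel[sel] <- hermite01_deriv(s_in, G[k], G[k + 1L],
                                      Tstep * v0, Tstep * v1) / Tstep
    }
    com_pos[n_total] <- G[n_steps + 1L]
    com_vel[n_total] <- at(core$v_raw, n_steps)

    # --- heel trajectories: backward belt drift in stance, C1 swing --------
    heel <- list(left = numeric(n_total), right = numeric(n_total))
    for (k in 0:n_steps) {
      side <- side_of(k)
      t_k <- (idx_hs(k) - 1L) / fs
      a <- max(idx_hs(k), 1L)
      b <- min(idx_to(k + 1L) - 1L, n_total)
      heel[[side]][a:b] <- at(H, k) - v_belt * (tvec[a:b] - t_k)
      if (k <= n_steps - 2L) {                  # swing to the next strike
        a2 <- idx_to(k + 1L)
        b2 <- idx_hs(k + 2L) - 1L
        dur <- (idx_hs(k + 2L) - a2) / fs
        y0 <- at(H, k) - v_belt * ((a2 - 1L) / fs - t_k)
        ssw <- (0:(b2 - a2)) / (idx_hs(k + 2L) - a2)
        heel[[side]][a2:b2] <- hermite01(ssw, y0, at(H, k + 2L),
                                         -v_belt * dur, -v_belt * dur)
      }
    }
    heel[[side_of(n_steps + 1L)]][n_total] <- at(H, n_steps + 1L)

    # --- per-leg stance kinetics ------------------------------------------
    L <- sps + dss                              # stance samples per leg
    u <- (0:(L - 1L)) / L
    tau_idx <- sps + seq_len(dss)
    tau <- (0:(dss - 1L)) / dss
    fwhm_smp <- config$noise_fwhm / 100 * sps
    st_grf <- stance_kinetics_matrix(
      core$eps, u, tau_idx, tau, stance_mu_grf(u, config$grf_amp),
      config$gain_grf, config$gain_shape, config$sigma_eta_grf, fwhm_smp)
    st_mom <- stance_kinetics_matrix(
      core$eps, u, tau_idx, tau, stance_mu_moment(u, config$moment_peak),
      config$gain_moment, config$gain_shape, config$sigma_eta_moment,
      fwhm_smp)
    grf <- list(left = numeric(n_total), right = numeric(n_total))
    mom <- list(left = numeric(n_total), right = numeric(n_total))
    for (k in 0:n_steps) {
      side <- side_of(k)
      a <- idx_hs(k); b <- a + L - 1L
      cols <- which(a:b >= 1L & a:b <= n_total)
      sel <- (a:b)[cols]
      grf[[side]][sel] <- st_grf[k + 1L, cols]
      mom[[side]][sel] <- st_mom[k + 1L, cols]
    }

    # --- combined CoP: butterfly with linear double-stance transfer --------
    ml_of <- function(k) ifelse(k %% 2L == 1L, 1, -1) * config$step_width / 2
    foot_cop <- function(k, idx) {
      t_k <- (idx_hs(k) - 1L) / fs
      at(H, k) - v_belt * (tvec[idx] - t_k) +
        config$cop_excursion * (idx - idx_hs(k)) / L
    }
    cop_ap <- numeric(n_total)
    cop_ml <- numeric(n_total)
    for (k in seq_len(n_steps)) {
      i0 <- idx_hs(k); i1 <- idx_hs(k + 1L) - 1L
      w <- c((0:(dss - 1L)) / dss, rep(1, sps - dss))
      idx <- i0:i1
      cop_ap[idx] <- (1 - w) * foot_cop(k - 1L, idx) + w * foot_cop(k, idx)
      cop_ml[idx] <- (1 - w) * ml_of(k - 1L) + w * ml_of(k)
    }
    cop_ap[n_total] <- foot_cop(n_steps, n_total)
    cop_ml[n_total] <- ml_of(n_steps)
    cop_ap <- cop_ap + smooth_noise_series(n_total, config$sigma_cop, fwhm_smp)
    cop_ml <- cop_ml + smooth_noise_series(n_total, config$sigma_cop, fwhm_smp)

    # --- ground-truth events ----------------------------------------------
    ks <- 1:(n_steps + 1L)
    hs_side <- side_of(ks)
    hs_smp <- idx_hs(ks)
    to_m <- 1:n_steps
    to_side <- side_of(to_m - 1L)
    to_smp <- idx_to(to_m)
    events <- new_gait_events(
      hs_left = hs_smp[hs_side == "left"],
      hs_right = hs_smp[hs_side == "right"],
      to_left = to_smp[to_side == "left"],
      to_right = to_smp[to_side == "right"],
      fs = fs)

    steps <- seq_len(n_steps)
    signals <- data.frame(
      time_s = tvec,
      cop_ap_m = cop_ap,
      cop_ml_m = cop_ml,
      grf_ap_left_N = grf$left,
      grf_ap_right_N = grf$right,
      grf_ap_combined_N = grf$left + grf$right,
      ankle_moment_left_Nm = mom$left,
      ankle_moment_right_Nm = mom$right,
      com_pos_ap_m = com_pos,
      com_vel_ap_mps = com_vel,
      heel_ap_left_m = heel$left,
      heel_ap_right_m = heel$right
    )
    structure(list(
      signals = signals,
      fs = fs,
      condition = config$condition,
      config = config,
      seed = seed,
      truth = list(
        events = events,
        fp_errors = core$eps[steps + 1L],
        fp_dev = core$fp_dev[steps + 1L],
        fp_raw = core$fp_raw[steps + 1L],
        states = data.frame(step = steps,
                            p_raw = core$p_raw[steps + 1L],
                            v_raw = core$v_raw[steps + 1L],
                            p_dev = core$p_dev[steps + 1L],
                            v_dev = core$v_dev[steps + 1L]),
        strike_pos = H,
        sps = sps, dss = dss, n_steps = n_steps
      )
    ), class = "synthetic_trial")
  })
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat("<synthetic_trial>", x$condition, "walking:", x$truth$n_steps, "steps @",
      x$fs, "Hz,", nrow(x$signals), "samples\n")
  cat("  foot placement error SD (truth):",
      format(stats::sd(x$truth$fp_errors), digits = 4), "m\n")
  invisible(x)
}
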
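# Phase-dependent linear foot placement model: regression of AP foot
# placement at heel strike on the CoM state (AP position relative to the
# stance foot, AP velocity) at every phase of the step.

#' CoM states relative to the per-step stance foot
#'
#' Re-references the CoM AP position matrix to the step's stance (trailing)
#' foot: one scalar AP reference per step is subtracted from the
#' corresponding row. The velocity matrix is passed through (frame
#' translation leaves it unchanged). Steps with a missing reference are
#' dropped with a warning.
#'
#' @param com_pos,com_vel steps x J matrices from a stride matrix.
#' @param stance_foot_ap numeric vector, one AP reference (m) per step.
#' @return list with `com_pos`, `com_vel` and the retained `steps` indices.
#' @export
compute_com_states <- function(com_pos, com_vel, stance_foot_ap) {
  stopifnot(is.matrix(com_pos), is.matrix(com_vel),
            all(dim(com_pos) == dim(com_vel)),
            length(stance_foot_ap) == nrow(com_pos))
  keep <- which(is.finite(stance_foot_ap))
  if (length(keep) < nrow(com_pos)) {
    warning("dropped ", nrow(com_pos) - length(keep),
            " step(s) without a stance-foot reference", call. = FALSE)
  }
  list(com_pos = com_pos[keep, , drop = FALSE] - stance_foot_ap[keep],
       com_vel = com_vel[keep, , drop = FALSE],
       steps = keep)
}

# Stance-foot AP reference per step from a stride matrix: the opening
# (stance) side's heel position at the step-opening heel strike (column 1).
stance_reference <- function(sm) {
  heel <- list(left = sm$channels$heel_ap_left_m,
               right = sm$channels$heel_ap_right_m)
  vapply(seq_len(nrow(sm$meta)),
         function(i) heel[[sm$meta$side[i]]][i, 1L], numeric(1))
}

# CoM state matrices straight from a stride matrix.
com_states_from_stride <- function(sm) {
  stopifnot(inherits(sm, "stride_matrix"))
  compute_com_states(sm$channels$com_pos_ap_m, sm$channels$com_vel_ap_mps,
                     stance_reference(sm))
}

#' AP foot placement from per-step heel positions
#'
#' Foot placement of a step is the AP distance between the leading foot
#' (landing at the step-closing heel strike) and the trailing (stance) foot
#' at that instant, de-meaned over the supplied steps so the subsequent
#' regression has a zero intercept.
#'
#' @param heel_ap_leading,heel_ap_trailing AP positions (m), one per step,
#'   both evaluated at the step-closing heel strike.
#' @return de-meaned foot placement vector (m) with the removed mean stored
#'   in attribute `"mean"`.
#' @export
compute_foot_placement <- function(heel_ap_leading, heel_ap_trailing) {
  stopifnot(length(heel_ap_leading) == length(heel_ap_trailing))
  if (length(heel_ap_leading) < 3) {
    stop("need at least 3 steps to de-mean foot placement", call. = FALSE)
  }
  fp_raw <- heel_ap_leading - heel_ap_trailing
  structure(fp_raw - mean(fp_raw), mean = mean(fp_raw))
}

# Foot placement from a stride matrix, de-meaned within each stance side
# (per-foot de-meaning; the sides are analyzed separately downstream).
fp_from_stride <- function(sm, demean_by_side = TRUE) {
  heel <- list(left = sm$channels$heel_ap_left_m,
               right = sm$channels$heel_ap_right_m)
  J <- ncol(heel$left)
  n <- nrow(sm$meta)
  lead <- vapply(seq_len(n), function(i)
    heel[[sm$meta$trailing_side[i]]][i, J], numeric(1))
  # note: at the step-closing heel strike the landing (leading) foot is the
  # contralateral of the step's opening side, i.e. meta$trailing_side
  trail <- vapply(seq_len(n), function(i)
    heel[[sm$meta$side[i]]][i, J], numeric(1))
  if (!demean_by_side) return(compute_foot_placement(lead, trail))
  fp <- numeric(n)
  for (sd in unique(sm$meta$side)) {
    sel <- sm$meta$side == sd
    fp[sel] <- compute_foot_placement(lead[sel], trail[sel])
  }
  fp
}

#' Fit the phase-dependent linear foot placement model
#'
#' At every phase sample j an independent ordinary-least-squares fit of
#' `FP_i = beta_pos(j) * CoM_pos_i(j) + beta_vel(j) * CoM_vel_i(j) + eps_i(j)`
#' is computed (two predictors, no intercept). All variables are de-meaned
#' over steps before fitting, which makes the zero-intercept model exact and
#' forces the residual mean at every phase to zero. Phases with a
#' rank-deficient predictor pair are flagged and get `NA` coefficients.
#'
#' @param fp foot placement vector (m), one per step.
#' @param com_pos,com_vel steps x J CoM state matrices.
#' @param phase optional phase axis (defaults to 0-100%).
#' @return an object of class `fpm_fit`: coefficient curves `beta_pos(j)`,
#'   `beta_vel(j)`, `r_squared(j)`, per-phase model `p_value(j)` (F test with
#'   2 and n-3 degrees of freedom; the de-meaning consumes one), the
#'   steps x J residual matrix, `flagged` phases, and `n_steps`.
#' @export
fit_fpm <- function(fp, com_pos, com_vel, phase = NULL) {
  stopifnot(is.matrix(com_pos), is.matrix(com_vel),
            all(dim(com_pos) == dim(com_vel)),
            length(fp) == nrow(com_pos))
  n <- length(fp)
  if (n < 3) stop("need at least 3 steps to fit", call. = FALSE)
  if (anyNA(fp) || anyNA(com_pos) || anyNA(com_vel)) {
    stop("missing values in fit inputs; drop incomplete steps first",
         call. = FALSE)
  }
  J <- ncol(com_pos)
  if (is.null(phase)) phase <- 100 * (0:(J - 1)) / (J - 1)
  y <- fp - mean(fp)
  P <- sweep(com_pos, 2, colMeans(com_pos))
  V <- sweep(com_vel, 2, colMeans(com_vel))
  Spp <- colSums(P^2); Svv <- colSums(V^2); Spv <- colSums(P * V)
  Spy <- colSums(P * y); Svy <- colSums(V * y)
  det <- Spp * Svv - Spv^2
  flagged <- det <= .Machine$double.eps * pmax(Spp * Svv, 1e-300) * 100
  det[flagged] <- NA_real_
  beta_pos <- (Svv * Spy - Spv * Svy) / det
  beta_vel <- (Spp * Svy - Spv * Spy) / det
  tss <- sum(y^2)
  fitted <- sweep(P, 2, beta_pos, "*") + sweep(V, 2, beta_vel, "*")
  residuals <- y - fitted
  rss <- colSums(residuals^2)
  r_squared <- if (tss > 0) pmin(pmax(1 - rss / tss, 0), 1) else
    rep(NA_real_, J)
  df2 <- n - 3
  fstat <- (r_squared / 2) / pmax((1 - r_squared) / df2, .Machine$double.xmin)
  p_value <- stats::pf(fstat, 2, df2, lower.tail = FALSE)
  structure(list(
    beta_pos = beta_pos, beta_vel = beta_vel,
    r_squared = r_squared, p_value = p_value,
    residuals = residuals, flagged = flagged,
    phase = phase, n_steps = n
  ), class = "fpm_fit")
}

#' @export
print.fpm_fit <- function(x, ...) {
  J <- length(x$phase)
  cat("<fpm_fit>", x$n_steps, "steps x", J, "phases\n")
  cat("  R^2 at heel strike:", format(x$r_squared[J], digits = 3),
      "; max R^2:", format(max(x$r_squared, na.rm = TRUE), digits = 3), "\n")
  cat("  beta_pos(100%):", format(x$beta_pos[J], digits = 3),
      "; beta_vel(100%):", format(x$beta_vel[J], digits = 3), "s\n")
  invisible(x)
}

#' Foot placement errors at heel strike
#'
#' The residuals of the foot placement model at phase 100% (the step-closing
#' heel strike). Positive values mean the foot was placed further forward
#' than the linear prediction from the CoM states.
#'
#' @param fit an [fit_fpm()] result.
#' @return numeric vector of per-step errors (m), mean exactly zero.
#' @export
foot_placement_errors <- function(fit) {
  stopifnot(inherits(fit, "fpm_fit"))
  fit$residuals[, ncol(fit$residuals)]
}

#' Summarize a foot placement error distribution
#'
#' Sample mean and SD, maximum-likelihood Gaussian parameters, and a
#' Shapiro-Wilk normality test (on a deterministic thinning if n exceeds the
#' test's 5000-sample limit). A zero-variance input is flagged degenerate.
#'
#' @param errors numeric vector of per-step errors (m), length >= 3.
#' @return list with `mean`, `sd`, `mle` (mean and SD with the 1/n
#'   denominator), `normality` (statistic, p_value, method) and `degenerate`.
#' @export
summarize_errors <- function(errors) {
  if (length(errors) < 3) stop("need at least 3 errors", call. = FALSE)
  m <- mean(errors)
  s <- stats::sd(errors)
  mle_sd <- sqrt(mean((errors - m)^2))
  if (mle_sd == 0) {
    return(list(mean = m, sd = s, mle = c(mean = m, sd = 0),
                normality = list(statistic = NA_real_, p_value = NA_real_,
                                 method = "none (degenerate)"),
                degenerate = TRUE))
  }
  x <- errors
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  sw <- stats::shapiro.test(x)
  list(mean = m, sd = s, mle = c(mean = m, sd = mle_sd),
       normality = list(statistic = unname(sw$statistic),
                        p_value = sw$p.value, method = sw$method),
       degenerate = FALSE)
}

#' Run the foot placement model on a stride matrix, per foot
#'
#' Convenience wrapper: extracts stance-referenced CoM states and de-meaned
#' foot placement from a stride matrix, fits the model separately for steps
#' opened by each side (per-foot analysis), and assembles a trial-wide
#' foot placement error vector.
#'
#' @param sm a [time_normalize()] stride matrix containing the CoM and heel
#'   channels.
#' @return list with `fits` (per side), `errors` (vector over all steps of
#'   `sm`, `NA` where a step was dropped), and `steps` metadata.
#' @export
fit_fpm_by_side <- function(sm) {
  stopifnot(inherits(sm, "stride_matrix"))
  st <- com_states_from_stride(sm)
  fp <- fp_from_stride(sm)
  meta <- sm$meta[st$steps, , drop = FALSE]
  fp <- fp[st$steps]
  errors <- rep(NA_real_, nrow(sm$meta))
  fits <- list()
  for (sd in unique(meta$side)) {
    sel <- which(meta$side == sd)
    fit <- fit_fpm(fp[sel] - mean(fp[sel]),
                   st$com_pos[sel, , drop = FALSE],
                   st$com_vel[sel, , drop = FALSE],
                   phase = sm$phase)
    fits[[sd]] <- fit
    errors[st$steps[sel]] <- foot_placement_errors(fit)
  }
  list(fits = fits, errors = errors, steps = sm$meta)
}
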
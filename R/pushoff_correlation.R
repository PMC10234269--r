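# Correlation of foot placement errors with kinetic time series over the
# subsequent double stance / full stride, and the extreme-error contrast.

#' Assemble analysis kinetic channels from a stride matrix
#'
#' Re-labels the per-leg channels per step. For each step i the reference
#' leg is the one whose heel strike opened it; `same_step` holds that leg's
#' series during step i (it is in stance throughout), and `next_step` row m
#' holds, for pairing with the error of step m-1, the trailing leg's series
#' during step m (the trailing leg of a double stance is the leg that opened
#' the previous step). The combined AP GRF needs no re-labeling.
#'
#' @param sm a [time_normalize()] stride matrix with the per-leg GRF and
#'   ankle moment channels.
#' @return named list (`combined_ap_grf`, `trailing_ap_grf`,
#'   `trailing_ankle_moment`) of `same_step` / `next_step` matrix pairs, as
#'   consumed by [pushoff_correlation_field()].
#' @export
kinetic_channels <- function(sm) {
  stopifnot(inherits(sm, "stride_matrix"))
  meta <- sm$meta
  n <- nrow(meta)
  pick_side <- function(left, right, sides) {
    out <- left
    is_r <- sides == "right"
    out[is_r, ] <- right[is_r, , drop = FALSE]
    out
  }
  grf_l <- sm$channels$grf_ap_left_N
  grf_r <- sm$channels$grf_ap_right_N
  mom_l <- sm$channels$ankle_moment_left_Nm
  mom_r <- sm$channels$ankle_moment_right_Nm
  combined <- if (!is.null(sm$channels$grf_ap_combined_N)) {
    sm$channels$grf_ap_combined_N
  } else {
    grf_l + grf_r
  }
  list(
    combined_ap_grf = list(same_step = combined, next_step = combined),
    trailing_ap_grf = list(
      same_step = pick_side(grf_l, grf_r, meta$side),
      next_step = pick_side(grf_l, grf_r, meta$trailing_side)),
    trailing_ankle_moment = list(
      same_step = pick_side(mom_l, mom_r, meta$side),
      next_step = pick_side(mom_l, mom_r, meta$trailing_side))
  )
}

# Per-column Pearson correlation and regression slope of columns of Y on x.
# Columns with (numerically) zero variance are masked.
cor_field_core <- function(x, Y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx <= 0) {
    stop("foot placement errors have zero variance: correlation undefined",
         call. = FALSE)
  }
  mu <- colMeans(Y)
  sxy <- as.vector(crossprod(xc, Y))
  syy <- pmax(colSums(Y^2) - n * mu^2, 0)
  masked <- syy <= max(syy, 1) * 1e-24
  r <- rep(NA_real_, ncol(Y))
  r[!masked] <- sxy[!masked] / sqrt(sxx * syy[!masked])
  slope <- sxy / sxx
  slope[masked] <- NA_real_
  resid <- sweep(Y, 2, mu) - outer(xc, slope)
  resid[, masked] <- NA_real_
  list(r = r, slope = slope, masked = masked, residuals = resid)
}

#' Correlate foot placement errors with a kinetic time series
#'
#' For every phase sample j, the Pearson correlation and regression slope of
#' `F_{i+1}(j) = beta(j) * eps_i + resid_{i+1}(j)` (lag `"next_step"`: the
#' error at the end of step i against the kinetics of step i+1) or its
#' same-step counterpart `F_i(j)` are computed. Phases where the kinetic
#' channel has no variance (e.g. a per-leg signal during that leg's swing,
#' which is identically zero) are masked. The last step, lacking a
#' following step, is excluded for `"next_step"`.
#'
#' @param errors per-step foot placement errors (m); `NA` steps are skipped.
#' @param kinetics steps x J kinetic matrix on the same step indexing.
#' @param lag `"next_step"` (default) or `"same_step"`.
#' @param phase optional phase axis.
#' @param subset optional error-step indices to use (e.g. steps of one foot).
#' @return an object of class `correlation_field` with `r(j)`, `slope(j)`
#'   (units of the kinetic signal per meter), `masked`, `residuals`,
#'   `n_pairs`, `phase`, `lag`.
#' @export
correlate_errors_kinetics <- function(errors, kinetics,
                                      lag = c("next_step", "same_step"),
                                      phase = NULL, subset = NULL) {
  lag <- match.arg(lag)
  stopifnot(is.matrix(kinetics), length(errors) == nrow(kinetics))
  n <- length(errors)
  idx <- if (is.null(subset)) seq_len(n) else intersect(subset, seq_len(n))
  if (lag == "next_step") idx <- idx[idx < n]
  idx <- idx[is.finite(errors[idx])]
  rows <- if (lag == "next_step") idx + 1L else idx
  if (length(idx) < 3) stop("need at least 3 valid pairs", call. = FALSE)
  core <- cor_field_core(errors[idx], kinetics[rows, , drop = FALSE])
  J <- ncol(kinetics)
  if (is.null(phase)) phase <- 100 * (0:(J - 1)) / (J - 1)
  structure(list(
    r = core$r, slope = core$slope, masked = core$masked,
    residuals = core$residuals, n_pairs = length(idx),
    phase = phase, lag = lag, error_steps = idx
  ), class = "correlation_field")
}

#' Full-stride correlation field for one kinetic signal
#'
#' Assembles, for the error of step i, the kinetic series of the reference
#' leg over the complete stride (step i followed by step i+1, spliced at the
#' step-i closing heel strike) and correlates it with the error per phase.
#' The double-stance extent of the corrective step is annotated.
#'
#' @param errors per-step foot placement errors (m).
#' @param channels a kinetic channel set ([kinetic_channels()] output or the
#'   `channels` element of [simulate_step_data()]).
#' @param signal one of `"combined_ap_grf"`, `"trailing_ap_grf"`,
#'   `"trailing_ankle_moment"`.
#' @param J_ds number of double-stance phase samples per step (for the
#'   phase-label annotation).
#' @param subset optional error-step indices (e.g. steps of one foot).
#' @return a `correlation_field` with an additional `phase_label` marking
#'   `pre_hs` (step i), `double_stance` and `post_ds` (step i+1); `phase`
#'   runs from -100% to +100% around the heel strike at which the error is
#'   evaluated.
#' @export
pushoff_correlation_field <- function(errors, channels,
                                      signal = c("trailing_ap_grf",
                                                 "trailing_ankle_moment",
                                                 "combined_ap_grf"),
                                      J_ds, subset = NULL) {
  signal <- match.arg(signal)
  ch <- channels[[signal]]
  stopifnot(!is.null(ch$same_step), !is.null(ch$next_step))
  n <- nrow(ch$same_step)
  J <- ncol(ch$same_step)
  idx <- if (is.null(subset)) seq_len(n - 1L) else
    intersect(subset, seq_len(n - 1L))
  idx <- idx[is.finite(errors[idx])]
  if (length(idx) < 3) stop("need at least 3 valid pairs", call. = FALSE)
  Y <- cbind(ch$same_step[idx, , drop = FALSE],
             ch$next_step[idx + 1L, , drop = FALSE])
  core <- cor_field_core(errors[idx], Y)
  phase <- c(100 * (0:(J - 1)) / (J - 1) - 100, 100 * (0:(J - 1)) / (J - 1))
  label <- c(rep("pre_hs", J),
             rep("double_stance", J_ds), rep("post_ds", J - J_ds))
  structure(list(
    r = core$r, slope = core$slope, masked = core$masked,
    residuals = core$residuals, n_pairs = length(idx),
    phase = phase, phase_label = label, signal = signal,
    lag = "full_stride", error_steps = idx
  ), class = "correlation_field")
}

#' @export
print.correlation_field <- function(x, ...) {
  cat("<correlation_field>", if (!is.null(x$signal)) x$signal else "",
      "(", x$lag, "):", x$n_pairs, "pairs,",
      length(x$r), "phases (", sum(x$masked), "masked )\n")
  pk <- which.max(abs(x$r))
  cat("  peak |r| =", format(x$r[pk], digits = 3), "at phase",
      format(x$phase[pk], digits = 3), "%\n")
  invisible(x)
}

#' @export
as.data.frame.correlation_field <- function(x, ...) {
  out <- data.frame(phase = x$phase, r = x$r, slope = x$slope,
                    n_pairs = x$n_pairs, masked = x$masked)
  if (!is.null(x$phase_label)) out$phase_label <- x$phase_label
  out
}

#' Contrast kinetics of the most positive and most negative errors
#'
#' Errors are sorted ascending (ties broken by step index); the k most
#' negative and k most positive select disjoint step sets whose paired
#' kinetic rows are averaged, mirroring the comparison of the ten largest
#' and ten smallest foot placement errors per participant.
#'
#' @param errors per-step foot placement errors (m).
#' @param kinetics steps x J kinetic matrix (same step indexing as `errors`).
#' @param k number of steps per tail (default 10); requires `2k <= n`.
#' @param lag pairing of error i with kinetics row i+1 (`"next_step"`,
#'   default), row i (`"same_step"`), or `"aligned"` when `kinetics` rows are
#'   already matched to the errors (e.g. full-stride rows).
#' @param subset optional error-step indices.
#' @return an object of class `extreme_contrast`: `mean_pos(j)`,
#'   `mean_neg(j)`, the selected step indices, `k`.
#' @export
extreme_error_contrast <- function(errors, kinetics, k = 10,
                                   lag = c("next_step", "same_step",
                                           "aligned"),
                                   subset = NULL) {
  lag <- match.arg(lag)
  stopifnot(is.matrix(kinetics))
  n <- length(errors)
  idx <- if (is.null(subset)) seq_len(n) else intersect(subset, seq_len(n))
  if (lag == "next_step") idx <- idx[idx < n]
  idx <- idx[is.finite(errors[idx])]
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  if (length(idx) < 2 * k) {
    stop("only ", length(idx), " steps available; need at least 2k = ",
         2 * k, " - use a smaller k", call. = FALSE)
  }
  ord <- idx[order(errors[idx], idx)]
  neg <- ord[seq_len(k)]
  pos <- ord[seq.int(length(ord) - k + 1L, length(ord))]
  rows <- function(i) switch(lag,
    next_step = i + 1L, same_step = i, aligned = i)
  kin_rows <- function(i) kinetics[rows(i), , drop = FALSE]
  structure(list(
    k = k,
    idx_pos = pos, idx_neg = neg,
    mean_pos = colMeans(kin_rows(pos)),
    mean_neg = colMeans(kin_rows(neg)),
    lag = lag
  ), class = "extreme_contrast")
}

#' @export
print.extreme_contrast <- function(x, ...) {
  cat("<extreme_contrast> k =", x$k, "per tail; mean(pos - neg) =",
      format(mean(x$mean_pos - x$mean_neg), digits = 3), "\n")
  invisible(x)
}
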
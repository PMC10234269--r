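# Gait event detection from the combined center of pressure, step
# segmentation, and two-window time normalization.

#' Gait event table
#'
#' Container for per-side heel-strike and toe-off sample indices. Events are
#' validated to be strictly increasing in time within each side.
#'
#' @param hs_left,hs_right,to_left,to_right integer sample indices.
#' @param fs sampling rate (Hz).
#' @return an object of class `gait_events`.
#' @export
new_gait_events <- function(hs_left, hs_right, to_left, to_right, fs) {
  chk <- function(x, nm) {
    x <- as.integer(x)
    if (is.unsorted(x, strictly = TRUE)) {
      stop("`", nm, "` must be strictly increasing", call. = FALSE)
    }
    x
  }
  structure(list(
    heel_strikes = list(left = chk(hs_left, "hs_left"),
                        right = chk(hs_right, "hs_right")),
    toe_offs = list(left = chk(to_left, "to_left"),
                    right = chk(to_right, "to_right")),
    fs = fs
  ), class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events> @", x$fs, "Hz: heel strikes L/R =",
      length(x$heel_strikes$left), "/", length(x$heel_strikes$right),
      "; toe-offs L/R =", length(x$toe_offs$left), "/",
      length(x$toe_offs$right), "\n")
  invisible(x)
}

#' @export
as.data.frame.gait_events <- function(x, ...) {
  rows <- do.call(rbind, lapply(c("left", "right"), function(sd) {
    rbind(
      data.frame(side = sd, type = "heel_strike",
                 sample = x$heel_strikes[[sd]]),
      data.frame(side = sd, type = "toe_off", sample = x$toe_offs[[sd]])
    )
  }))
  rows$time_s <- (rows$sample - 1) / x$fs
  rows[order(rows$sample), ]
}

# Refine an event location to the kink (slope discontinuity) of the ML
# trajectory within [a, b]: differences of a piecewise-linear signal vanish
# away from its kinks, while smooth measurement noise has almost no
# high-order difference content, so the kink dominates the local fourth
# difference.
refine_kink <- function(ml, a, b) {
  n <- length(ml)
  a <- max(3L, a)
  b <- min(n - 2L, b)
  if (b < a) return(NA_integer_)
  win <- a:b
  d4 <- ml[win + 2L] - 4 * ml[win + 1L] + 6 * ml[win] -
    4 * ml[win - 1L] + ml[win - 2L]
  win[which.max(abs(d4))]
}

#' Detect gait events from the center-of-pressure butterfly
#'
#' Heel strikes and toe-offs are recovered from the combined CoP trajectory:
#' during single stance the mediolateral (ML) CoP dwells under the stance
#' foot, and over each double stance it transfers rapidly to the other foot,
#' tracing the characteristic "butterfly". Detection is three-staged and
#' needs no threshold in physical units:
#'
#' 1. *Transfers*: after Gaussian smoothing, the ML plateau levels are
#'    estimated and transfers located as hysteresis crossings of the
#'    midline, which are alternating by construction. Spurious
#'    crossing pairs closer than `min_step_time` are discarded.
#' 2. *Coarse edges*: the transfer width is estimated from the plateau
#'    separation and the peak ML slope; onset and completion are placed half
#'    a width on either side of the crossing.
#' 3. *Refinement*: each edge is sharpened to the local slope discontinuity
#'    (maximal fourth difference) of the raw ML signal, which dominates
#'    smooth measurement noise.
#'
#' The onset of a transfer is the heel strike of the landing side; its
#' completion is the toe-off of the vacating side. The ML sign convention is
#' positive towards the left foot, so an upward transfer lands on the left.
#'
#' @param cop_ap,cop_ml combined CoP AP and ML series (m), same length.
#'   (`cop_ap` is accepted for interface completeness; the ML trace carries
#'   the event information.)
#' @param fs sampling rate (Hz).
#' @param min_step_time minimal plausible step duration (s).
#' @param smooth_window full width at half maximum of the detector's Gaussian
#'   smoothing (s).
#' @return a [new_gait_events()] object.
#' @export
detect_events_from_cop <- function(cop_ap, cop_ml, fs,
                                   min_step_time = 0.3,
                                   smooth_window = 0.03) {
  if (length(cop_ap) != length(cop_ml)) {
    stop("`cop_ap` and `cop_ml` must have the same length", call. = FALSE)
  }
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  n <- length(cop_ml)
  ml_s <- smooth_series(cop_ml, smooth_window * fs)

  # plateau levels and midline; degenerate (constant) input has no events
  med <- stats::median(ml_s)
  hi <- stats::median(ml_s[ml_s > med])
  lo <- stats::median(ml_s[ml_s < med])
  if (!is.finite(hi) || !is.finite(lo) || hi - lo <= 0 ||
      hi - lo < 4 * stats::mad(diff(ml_s))) {
    stop("no gait events detected: mediolateral CoP shows no transfers",
         call. = FALSE)
  }
  mid <- (hi + lo) / 2
  hyst <- 0.25 * (hi - lo)

  # hysteresis midline crossings: alternating transfer markers
  state <- if (ml_s[1] > mid) 1L else -1L
  crossings <- integer(0)
  dirs <- integer(0)
  backtrack <- function(i, dir) {
    # from the hysteresis trigger, walk back to the actual midline crossing
    j <- i
    while (j > 1L && (ml_s[j - 1L] - mid) * dir > 0) j <- j - 1L
    j
  }
  for (i in seq_len(n)) {
    if (state == -1L && ml_s[i] > mid + hyst) {
      state <- 1L
      crossings <- c(crossings, backtrack(i, 1L))
      dirs <- c(dirs, 1L)
    } else if (state == 1L && ml_s[i] < mid - hyst) {
      state <- -1L
      crossings <- c(crossings, backtrack(i, -1L))
      dirs <- c(dirs, -1L)
    }
  }
  # a crossing pair closer than the minimal step time is a noise toggle:
  # drop both (the stronger, persisting level is the one that remains)
  min_gap <- round(min_step_time * fs)
  repeat {
    gaps <- diff(crossings)
    bad <- which(gaps < min_gap)
    if (!length(bad)) break
    drop <- c(bad[1], bad[1] + 1L)
    crossings <- crossings[-drop]
    dirs <- dirs[-drop]
  }
  if (length(crossings) < 3) {
    stop("fewer than 3 steps detected", call. = FALSE)
  }
  if (any(diff(dirs) == 0)) {
    bad <- which(diff(dirs) == 0)
    stop("non-alternating mediolateral transfers at samples ",
         paste(crossings[bad], collapse = ", "), call. = FALSE)
  }

  # transfer width from plateau separation and peak ML slope
  d <- c(ml_s[2] - ml_s[1],
         (ml_s[3:n] - ml_s[1:(n - 2)]) / 2,
         ml_s[n] - ml_s[n - 1]) * fs
  # the midline crossing sits at the ramp center, where the smoothed slope
  # is unbiased; the median over transfers gives a stable width estimate
  mid_slope <- stats::median(abs(d[crossings]))
  width <- (hi - lo) / mid_slope * fs  # in samples
  inner <- max(2L, round(width / 4))
  outer <- max(4L, round(1.2 * width))

  # pass 1: independent kink refinement of both transfer edges
  onset <- offset <- integer(length(crossings))
  keep <- logical(length(crossings))
  for (m in seq_along(crossings)) {
    cc <- crossings[m]
    if (cc - outer < 3L || cc + outer > n - 2L) next
    onset[m] <- refine_kink(cop_ml, cc - outer, cc - inner)
    offset[m] <- refine_kink(cop_ml, cc + inner, cc + outer)
    keep[m] <- TRUE
  }
  # pass 2: the double-stance sub-window has (nearly) fixed duration within
  # a condition, so the two kinks of a transfer are a fixed distance apart;
  # re-estimate both jointly, summing the kink evidence of edge pairs at
  # the consensus spacing (+/- a small slack)
  if (sum(keep) >= 5L) {
    wd <- round(stats::median((offset - onset)[keep]))
    slack <- max(2L, round(width / 8))
    idx4 <- 3L:(n - 2L)
    d4 <- rep(0, n)
    d4[idx4] <- abs(cop_ml[idx4 + 2L] - 4 * cop_ml[idx4 + 1L] +
                      6 * cop_ml[idx4] - 4 * cop_ml[idx4 - 1L] +
                      cop_ml[idx4 - 2L])
    for (m in which(keep)) {
      cc <- crossings[m]
      cand_o <- max(3L, cc - outer):(cc - inner)
      best <- c(-Inf, onset[m], offset[m])
      for (o in cand_o) {
        es <- (o + wd - slack):(o + wd + slack)
        es <- es[es >= cc + inner & es <= min(n - 2L, cc + outer)]
        if (!length(es)) next
        sc <- d4[o] + max(d4[es])
        if (sc > best[1]) {
          best <- c(sc, o, es[which.max(d4[es])])
        }
      }
      if (is.finite(best[1])) {
        onset[m] <- best[2]
        offset[m] <- best[3]
      }
    }
  }
  if (sum(keep) < 3) stop("fewer than 3 steps detected", call. = FALSE)
  onset <- onset[keep]; offset <- offset[keep]; dirs <- dirs[keep]
  land_side <- ifelse(dirs > 0, "left", "right")
  vacate_side <- ifelse(dirs > 0, "right", "left")
  new_gait_events(
    hs_left = onset[land_side == "left"],
    hs_right = onset[land_side == "right"],
    to_left = offset[vacate_side == "left"],
    to_right = offset[vacate_side == "right"],
    fs = fs)
}

#' Segment a trial into steps
#'
#' A step runs from one heel strike to the contralateral heel strike. Its
#' initial double stance ends at the toe-off of the vacating (trailing) leg,
#' i.e. the leg whose heel strike opened the previous step. Steps without a
#' toe-off of the expected side inside them are dropped with a warning.
#'
#' @param events a [new_gait_events()] object.
#' @return data.frame with one row per step: `step`, `side` (the side whose
#'   heel strike opens the step), `trailing_side` (the side that toes off in
#'   the step's double stance), samples `hs`, `to`, `next_hs`, and durations.
#'   Sampling rate kept as attribute `fs`.
#' @export
segment_steps <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  fs <- events$fs
  hs <- rbind(
    data.frame(side = "left", sample = events$heel_strikes$left),
    data.frame(side = "right", sample = events$heel_strikes$right)
  )
  hs <- hs[order(hs$sample), ]
  if (nrow(hs) < 2) stop("need at least two heel strikes", call. = FALSE)
  if (any(hs$side[-1] == hs$side[-nrow(hs)])) {
    bad <- which(hs$side[-1] == hs$side[-nrow(hs)])
    stop("heel strikes do not alternate sides at samples ",
         paste(hs$sample[bad + 1L], collapse = ", "), call. = FALSE)
  }
  out <- vector("list", nrow(hs) - 1L)
  dropped <- integer(0)
  for (i in seq_len(nrow(hs) - 1L)) {
    side <- hs$side[i]
    trailing <- if (side == "left") "right" else "left"
    a <- hs$sample[i]; b <- hs$sample[i + 1L]
    tos <- events$toe_offs[[trailing]]
    to <- tos[tos > a & tos < b]
    if (length(to) != 1L) {
      dropped <- c(dropped, i)
      next
    }
    out[[i]] <- data.frame(step = i, side = side, trailing_side = trailing,
                           hs = a, to = to, next_hs = b)
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped), " step(s) without a unique ",
            "trailing toe-off: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  steps <- do.call(rbind, out)
  if (is.null(steps) || nrow(steps) == 0) {
    stop("no complete steps after segmentation", call. = FALSE)
  }
  steps$ds_duration <- (steps$to - steps$hs) / fs
  steps$ss_duration <- (steps$next_hs - steps$to) / fs
  if (any(steps$ds_duration <= 0)) {
    stop("non-positive double-stance duration", call. = FALSE)
  }
  attr(steps, "fs") <- fs
  steps
}

#' Time-normalize step windows onto a fixed two-window phase grid
#'
#' Each step is split at the trailing leg's toe-off into its double-stance
#' and single-stance sub-windows, and each sub-window is resampled
#' independently onto a fixed number of phase samples (`J_ds`, `J_ss`), so
#' that within a condition every row shares the same grid and the last
#' column (phase 100%) is the contralateral heel strike. Original durations
#' are preserved in the step metadata.
#'
#' @param signals data.frame with a `time_s` column plus signal channels.
#' @param steps step table from [segment_steps()].
#' @param J_ds,J_ss number of phase samples for the double- and single-stance
#'   sub-windows (>= 2).
#' @param method interpolation: `"linear"` (exact on constants and ramps, no
#'   overshoot on kinetic transients) or `"cubic"`.
#' @return an object of class `stride_matrix`: list with `channels` (named
#'   list of steps x (J_ds + J_ss) matrices), `phase` (0-100), `J_ds`,
#'   `J_ss`, `meta` (the step table of retained steps), `fs`, `method`.
#' @export
time_normalize <- function(signals, steps, J_ds = 20, J_ss = 80,
                           method = c("linear", "cubic")) {
  method <- match.arg(method)
  if (J_ds < 2 || J_ss < 2) stop("J_ds and J_ss must be >= 2", call. = FALSE)
  stopifnot(is.data.frame(signals), "time_s" %in% names(signals))
  fs <- attr(steps, "fs")
  tt <- signals$time_s
  # drop steps whose sub-windows are shorter than 2 samples
  ok <- (steps$to - steps$hs) >= 2L & (steps$next_hs - steps$to) >= 2L
  if (any(!ok)) {
    warning("dropped ", sum(!ok), " step(s) with a sub-window shorter than ",
            "2 samples", call. = FALSE)
    steps <- steps[ok, , drop = FALSE]
  }
  if (nrow(steps) == 0) stop("no steps left to normalize", call. = FALSE)
  t_hs <- tt[steps$hs]; t_to <- tt[steps$to]; t_next <- tt[steps$next_hs]
  J <- J_ds + J_ss
  grid_times <- matrix(NA_real_, nrow(steps), J)
  f_ds <- (0:(J_ds - 1)) / J_ds
  f_ss <- (0:(J_ss - 1)) / (J_ss - 1)
  for (i in seq_len(nrow(steps))) {
    grid_times[i, ] <- c(t_hs[i] + (t_to[i] - t_hs[i]) * f_ds,
                         t_to[i] + (t_next[i] - t_to[i]) * f_ss)
  }
  xout <- as.vector(t(grid_times))
  chan_names <- setdiff(names(signals), "time_s")
  channels <- lapply(chan_names, function(nm) {
    y <- signals[[nm]]
    vals <- if (method == "linear") {
      stats::approx(tt, y, xout = xout, rule = 2)$y
    } else {
      stats::splinefun(tt, y, method = "fmm")(xout)
    }
    matrix(vals, nrow(steps), J, byrow = TRUE)
  })
  names(channels) <- chan_names
  structure(list(
    channels = channels,
    phase = 100 * (0:(J - 1)) / (J - 1),
    J_ds = as.integer(J_ds), J_ss = as.integer(J_ss),
    meta = steps, fs = fs, method = method
  ), class = "stride_matrix")
}

#' @export
print.stride_matrix <- function(x, ...) {
  cat("<stride_matrix>", nrow(x$meta), "steps x", x$J_ds + x$J_ss,
      "phase samples (", x$J_ds, "double stance +", x$J_ss,
      "single stance );", length(x$channels), "channels\n")
  invisible(x)
}
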
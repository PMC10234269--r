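# Shared fixtures: small configurations and truth-matching utilities.

small_config <- function(...) gait_config(n_strides = 20, ...)

# fraction of truth events matched within `tol` samples by detected events
event_match_rate <- function(truth, detected, tol = 1) {
  if (length(truth) == 0) return(NA_real_)
  mean(vapply(truth, function(x) any(abs(detected - x) <= tol), logical(1)))
}

# pooled match rate over both sides and both event types
trial_match_rate <- function(truth_events, detected_events, tol = 1,
                             skip_boundary = 0L) {
  pairs <- list(
    c("heel_strikes", "left"), c("heel_strikes", "right"),
    c("toe_offs", "left"), c("toe_offs", "right"))
  tot <- 0; hit <- 0
  for (p in pairs) {
    tru <- truth_events[[p[1]]][[p[2]]]
    if (skip_boundary > 0) {
      rng <- range(unlist(truth_events$heel_strikes))
      tru <- tru[tru > rng[1] + skip_boundary & tru < rng[2] - skip_boundary]
    }
    det <- detected_events[[p[1]]][[p[2]]]
    tot <- tot + length(tru)
    hit <- hit + sum(vapply(tru, function(x) any(abs(det - x) <= tol),
                            logical(1)))
  }
  hit / tot
}

# closed-form two-predictor no-intercept OLS (normal equations), used as an
# independent oracle for fit_fpm
ols2_oracle <- function(y, x1, x2) {
  A <- matrix(c(sum(x1^2), sum(x1 * x2), sum(x1 * x2), sum(x2^2)), 2, 2)
  b <- c(sum(x1 * y), sum(x2 * y))
  solve(A, b)
}
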
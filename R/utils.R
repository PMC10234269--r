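# Internal numerical helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so package functions are deterministic without clobbering the global
#' stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Gaussian smoothing matrix over columns. Columns are scaled to unit L2 norm,
# so white noise smoothed by it keeps unit pointwise SD (the kernel trades
# independence for smoothness, not amplitude).
gaussian_smooth_matrix <- function(n, fwhm) {
  stopifnot(n >= 1)
  if (fwhm <= 0) return(diag(n))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  sweep(K, 2, sqrt(colSums(K^2)), "/")
}

# n_row x n_col matrix of smooth Gaussian noise with pointwise SD `sd` and
# the stated full-width-at-half-maximum (in columns).
smooth_noise <- function(n_row, n_col, sd, fwhm) {
  if (sd == 0 || n_row == 0L) return(matrix(0, n_row, n_col))
  matrix(stats::rnorm(n_row * n_col), n_row, n_col) %*%
    gaussian_smooth_matrix(n_col, fwhm) * sd
}

# Gaussian smoothing of a single series (edge-replicated), used by the event
# detector. `fwhm` in samples.
smooth_series <- function(x, fwhm) {
  if (fwhm <= 0) return(x)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1L):(half + n)]
}

# Cubic Hermite interpolation on s in [0, 1] with endpoint values y0, y1 and
# endpoint derivatives d0, d1 (already scaled to the unit interval).
hermite01 <- function(s, y0, y1, d0, d1) {
  s2 <- s * s
  s3 <- s2 * s
  (2 * s3 - 3 * s2 + 1) * y0 + (s3 - 2 * s2 + s) * d0 +
    (-2 * s3 + 3 * s2) * y1 + (s3 - s2) * d1
}

# Derivative of hermite01 with respect to s.
hermite01_deriv <- function(s, y0, y1, d0, d1) {
  s2 <- s * s
  (6 * s2 - 6 * s) * y0 + (3 * s2 - 4 * s + 1) * d0 +
    (-6 * s2 + 6 * s) * y1 + (3 * s2 - 2 * s) * d1
}

# Stationary covariance of x_{k+1} = A x_k + w, w ~ N(0, Q), by solving
# vec(S) = (I - A (x) A)^{-1} vec(Q). Requires spectral radius of A < 1.
stationary_cov <- function(A, Q) {
  M <- diag(4) - kronecker(A, A)
  matrix(solve(M, as.vector(Q)), 2, 2)
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

# Column means/SDs for a matrix with possible NA columns.
col_sds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sqrt(pmax(colSums(X^2) - n * mu^2, 0) / (n - 1))
}
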
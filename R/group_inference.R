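# Group-level aggregation of correlation fields (Fisher r-to-z) and
# permutation-based one-dimensional cluster inference on phase-indexed
# statistic fields.

#' Fisher r-to-z group mean of correlations
#'
#' Averages correlation coefficients by (1) transforming to z = atanh(r),
#' which makes them approximately normal, (2) averaging the z values, and
#' (3) back-transforming with tanh. Accepts a vector (one phase) or a
#' participants x J matrix (per-column means). Values with |r| >= 1 are
#' clipped to 1 - 1e-12 with a warning.
#'
#' @param r correlations, vector or matrix.
#' @param na.rm drop missing values (masked phases) before averaging.
#' @return the back-transformed mean, scalar or per-column vector.
#' @examples
#' fisher_mean(c(0.3, 0.5))  # 0.4046
#' @export
fisher_mean <- function(r, na.rm = TRUE) {
  if (length(r) == 0) stop("empty input", call. = FALSE)
  clip <- function(x) {
    bad <- is.finite(x) & abs(x) >= 1
    if (any(bad)) {
      warning("clipping ", sum(bad), " correlation(s) with |r| >= 1",
              call. = FALSE)
      x[bad] <- sign(x[bad]) * (1 - 1e-12)
    }
    x
  }
  if (is.matrix(r)) {
    tanh(colMeans(atanh(clip(r)), na.rm = na.rm))
  } else {
    tanh(mean(atanh(clip(r)), na.rm = na.rm))
  }
}

#' Pointwise t-statistic field across participants
#'
#' One-sample t statistic at every phase sample of a participants x J matrix
#' (for a paired design, pass the matrix of per-participant difference
#' curves via `data2`). Phases with zero between-participant variance are
#' flagged: infinite t when the mean is non-zero, zero otherwise.
#'
#' @param data participants x J matrix.
#' @param data2 optional second matrix for a paired design; the test is then
#'   one-sample on `data - data2`.
#' @return list with `t` (length J), `df`, `flagged` (zero-variance phases),
#'   `n`.
#' @export
spm_t_field <- function(data, data2 = NULL) {
  stopifnot(is.matrix(data))
  if (!is.null(data2)) {
    stopifnot(all(dim(data2) == dim(data)))
    data <- data - data2
  }
  n <- nrow(data)
  if (n < 3) stop("need at least 3 participants", call. = FALSE)
  mu <- colMeans(data)
  s <- col_sds(data)
  flagged <- !is.na(s) & s == 0 & is.finite(mu)
  tval <- mu / (s / sqrt(n))
  tval[flagged & mu != 0] <- Inf * sign(mu[flagged & mu != 0])
  tval[flagged & mu == 0] <- 0
  list(t = tval, df = n - 1L, flagged = flagged, n = n)
}

# Maximal supra-threshold clusters (two-sided) of a t field; NA phases break
# contiguity. Cluster statistic: sum of |t| over the run.
find_clusters <- function(tval, thr) {
  supra <- ifelse(is.na(tval), FALSE, abs(tval) > thr)
  sgn <- sign(tval)
  sgn[is.na(sgn)] <- 0
  # run boundaries: clusters end where supra-threshold stops or sign flips
  runs <- rle(paste0(supra, "_", ifelse(supra, sgn, 0)))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- grepl("^TRUE", runs$values)
  if (!any(keep)) {
    return(data.frame(j_start = integer(0), j_end = integer(0),
                      sign = integer(0), stat = numeric(0)))
  }
  data.frame(
    j_start = starts[keep],
    j_end = ends[keep],
    sign = as.integer(sub("^TRUE_", "", runs$values[keep])),
    stat = vapply(which(keep), function(i) {
      sum(abs(tval[starts[i]:ends[i]]))
    }, numeric(1))
  )
}

max_cluster_stat <- function(tval, thr) {
  cl <- find_clusters(tval, thr)
  if (nrow(cl) == 0) 0 else max(cl$stat)
}

#' Permutation-based 1D cluster inference
#'
#' Tests whether a group of phase-indexed curves has non-zero mean anywhere,
#' respecting the smoothness (interdependence) of neighboring phase samples:
#' the observed t field is thresholded at the two-sided pointwise t critical
#' value for `alpha`, contiguous supra-threshold runs form clusters (summed
#' |t| as cluster statistic), and their p-values are the fraction of
#' sign-flip permutations whose *maximum* cluster statistic reaches the
#' observed one. If `n_permutations` is at least the number of distinct sign
#' patterns, the permutation distribution is enumerated exhaustively (and a
#' message emitted). Deterministic given `seed`.
#'
#' @param data participants x J matrix (e.g. Fisher-z correlation curves);
#'   for a paired test pass difference curves, or use `data2`.
#' @param data2 optional paired second matrix.
#' @param alpha significance level (also the cluster-forming pointwise
#'   level); default 0.05.
#' @param n_permutations number of sign-flip permutations (>= 100).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return an object of class `cluster_inference`: the observed `t` field,
#'   `df`, cluster-forming `threshold`, `clusters` data.frame (`j_start`,
#'   `j_end` phase-sample indices, `sign`, `stat`, `p_value`,
#'   `significant`), `alpha`, `n_permutations` actually used, `exhaustive`.
#' @export
permutation_cluster_inference <- function(data, data2 = NULL, alpha = 0.05,
                                          n_permutations = 10000, seed) {
  stopifnot(is.matrix(data))
  if (!is.null(data2)) data <- data - data2
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (n_permutations < 100) {
    stop("need at least 100 permutations", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n <- nrow(data)
  if (n < 3) stop("need at least 3 participants", call. = FALSE)
  valid <- !apply(data, 2, anyNA)
  Y <- data[, valid, drop = FALSE]
  obs <- spm_t_field(data)
  thr <- stats::qt(1 - alpha / 2, df = n - 1L)
  clusters <- find_clusters(obs$t, thr)

  n_patterns <- 2^n
  exhaustive <- is.finite(n_patterns) && n_permutations >= n_patterns
  S <- if (exhaustive) {
    message("enumerating all ", n_patterns, " sign patterns exhaustively")
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    with_seed(seed,
      matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
             n_permutations, n))
  }
  B <- nrow(S)
  ss <- colSums(Y^2)
  M <- (S %*% Y) / n
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  Tm <- M / sqrt(pmax(V, 0) / n)
  Tm[!is.finite(Tm)] <- 0
  # re-embed valid columns so contiguity matches the observed field
  perm_max <- numeric(B)
  tmpl <- rep(NA_real_, ncol(data))
  for (b in seq_len(B)) {
    tmpl[valid] <- Tm[b, ]
    perm_max[b] <- max_cluster_stat(tmpl, thr)
  }
  if (nrow(clusters) > 0) {
    if (exhaustive) {
      clusters$p_value <- vapply(clusters$stat,
        function(s) mean(perm_max >= s), numeric(1))
    } else {
      clusters$p_value <- vapply(clusters$stat,
        function(s) (1 + sum(perm_max >= s)) / (B + 1), numeric(1))
    }
    clusters$significant <- clusters$p_value <= alpha
  } else {
    clusters$p_value <- numeric(0)
    clusters$significant <- logical(0)
  }
  structure(list(
    t = obs$t, df = obs$df, threshold = thr, clusters = clusters,
    alpha = alpha, n_permutations = B, exhaustive = exhaustive,
    flagged = obs$flagged
  ), class = "cluster_inference")
}

#' @export
print.cluster_inference <- function(x, ...) {
  cat("<cluster_inference> threshold |t| >",
      format(x$threshold, digits = 4), "(alpha =", x$alpha, ", df =",
      x$df, ");", x$n_permutations, "permutations",
      if (x$exhaustive) "(exhaustive)" else "", "\n")
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster [%d, %d] sign %+d stat %.2f p = %.4f%s\n",
                  x$clusters$j_start[i], x$clusters$j_end[i],
                  x$clusters$sign[i], x$clusters$stat[i],
                  x$clusters$p_value[i],
                  if (x$clusters$significant[i]) " *" else ""))
    }
  }
  invisible(x)
}

#' Group-level correlation field with cluster inference
#'
#' Aggregates per-participant correlation curves via Fisher r-to-z, returns
#' the back-transformed group mean curve, and tests the z curves against
#' zero with [permutation_cluster_inference()]. Masked (NA) phases are
#' excluded from testing but kept in the output.
#'
#' @param r_matrix participants x J matrix of correlation curves (each row
#'   typically the z-space average of a participant's per-foot fields).
#' @param phase optional phase axis.
#' @param alpha significance level.
#' @param n_permutations sign-flip permutations.
#' @param seed RNG seed.
#' @return an object of class `group_field`: `mean_r(j)`, `z`
#'   (participants x J), `n_participants`, `inference`
#'   (a `cluster_inference`), `clusters` annotated with phase bounds.
#' @export
group_correlation_field <- function(r_matrix, phase = NULL, alpha = 0.05,
                                    n_permutations = 10000, seed) {
  stopifnot(is.matrix(r_matrix))
  J <- ncol(r_matrix)
  if (is.null(phase)) phase <- 100 * (0:(J - 1)) / (J - 1)
  bad <- is.finite(r_matrix) & abs(r_matrix) >= 1
  if (any(bad)) {
    r_matrix[bad] <- sign(r_matrix[bad]) * (1 - 1e-12)
    warning("clipped ", sum(bad), " correlation(s) with |r| >= 1",
            call. = FALSE)
  }
  z <- atanh(r_matrix)
  mean_r <- tanh(colMeans(z))
  inf <- permutation_cluster_inference(z, alpha = alpha,
                                       n_permutations = n_permutations,
                                       seed = seed)
  cl <- inf$clusters
  if (nrow(cl) > 0) {
    cl$phase_start <- phase[cl$j_start]
    cl$phase_end <- phase[cl$j_end]
  }
  structure(list(
    mean_r = mean_r, z = z, phase = phase,
    n_participants = nrow(r_matrix),
    inference = inf, clusters = cl, alpha = alpha
  ), class = "group_field")
}

#' @export
print.group_field <- function(x, ...) {
  cat("<group_field>", x$n_participants, "participants x",
      length(x$mean_r), "phases\n")
  cat("  peak |mean r| =",
      format(max(abs(x$mean_r), na.rm = TRUE), digits = 3), "\n")
  print(x$inference)
  invisible(x)
}
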
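# Simulation-based calibration of the group-level inference.

#' Per-participant correlation curve from step-level simulation
#'
#' Simulates one synthetic participant with the step-level generator, computes
#' the full-stride error-kinetics correlation field separately for the steps
#' of each foot, and averages the two curves in Fisher-z space — the same
#' construction the full pipeline uses per participant.
#'
#' @param config a [gait_config()].
#' @param seed RNG seed for this participant.
#' @param signal kinetic signal id.
#' @return numeric correlation curve (length 2 J), `NA` at masked phases.
#' @export
simulate_participant_curve <- function(config, seed,
                                       signal = "combined_ap_grf") {
  sdd <- simulate_step_data(config, seed = seed)
  curves <- do.call(rbind, lapply(c(1L, 2L), function(par) {
    sel <- seq.int(par, sdd$n_steps, by = 2L)
    pushoff_correlation_field(sdd$errors, sdd$channels, signal = signal,
                              J_ds = config$J_ds, subset = sel)$r
  }))
  fisher_mean(pmin(pmax(curves, -1 + 1e-12), 1 - 1e-12), na.rm = FALSE)
}

#' Family-wise error calibration of the permutation cluster test
#'
#' Runs replicate null experiments: the kinetic feedback gain is set to zero
#' so foot placement errors and kinetics are independent by construction,
#' a group of synthetic participants is simulated, the error-kinetics
#' correlation pipeline is applied, and the group's Fisher-z curves are
#' tested with [permutation_cluster_inference()] at the nominal level. The
#' empirical family-wise false-positive rate is the fraction of replicates
#' with at least one significant cluster; under a calibrated test it matches
#' the nominal level.
#'
#' @param n_replicates number of independent null experiments.
#' @param n_participants synthetic participants per experiment.
#' @param config generator configuration; any kinetic gains are overridden
#'   to zero.
#' @param alpha nominal significance level.
#' @param n_permutations sign-flip permutations per test.
#' @param seed master seed; all replicate and permutation seeds derive
#'   from it.
#' @param signal kinetic signal used for the correlation fields.
#' @return list with `fwer`, `hits`, `n_replicates`, `alpha`.
#' @export
fwer_calibration <- function(n_replicates = 200, n_participants = 20,
                             config = gait_config(), alpha = 0.05,
                             n_permutations = 1000, seed = 1L,
                             signal = "combined_ap_grf") {
  config$gain_grf <- 0
  config$gain_moment <- 0
  validate_gait_config(config)
  seeds <- with_seed(seed, list(
    sim = matrix(sample.int(2^31 - 2, n_replicates * n_participants),
                 n_replicates, n_participants),
    perm = sample.int(2^31 - 2, n_replicates)))
  hits <- 0L
  for (rep in seq_len(n_replicates)) {
    curves <- do.call(rbind, lapply(seq_len(n_participants), function(pp) {
      simulate_participant_curve(config, seeds$sim[rep, pp], signal)
    }))
    ci <- permutation_cluster_inference(atanh(curves), alpha = alpha,
                                        n_permutations = n_permutations,
                                        seed = seeds$perm[rep])
    hits <- hits + as.integer(any(ci$clusters$significant))
  }
  list(fwer = hits / n_replicates, hits = hits,
       n_replicates = n_replicates, alpha = alpha)
}
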
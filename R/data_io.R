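# Columnar trial files, truth sidecars, pipeline configuration and the
# end-to-end orchestrator.

trial_required_columns <- c(
  "time_s", "cop_ap_m", "cop_ml_m", "grf_ap_left_N", "grf_ap_right_N",
  "ankle_moment_left_Nm", "ankle_moment_right_Nm", "com_pos_ap_m",
  "com_vel_ap_mps", "heel_ap_left_m", "heel_ap_right_m")

#' Write a gait trial to a columnar text file
#'
#' Plain CSV with a small `#`-prefixed metadata header (sampling rate,
#' condition, participant, leg length). Numeric values are written with 17
#' significant digits, so a write/read round trip reproduces the doubles
#' bit-identically.
#'
#' @param trial a `synthetic_trial`, a `gait_trial`, or a data.frame of
#'   signals (then `fs` etc. must be given).
#' @param path output file path.
#' @param fs,condition,participant,leg_length metadata; taken from `trial`
#'   when it carries them.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, fs = NULL, condition = NULL,
                        participant = "synthetic", leg_length = NA_real_) {
  if (inherits(trial, c("synthetic_trial", "gait_trial"))) {
    signals <- trial$signals
    fs <- trial$fs
    condition <- trial$condition
    if (!is.null(trial$config)) leg_length <- trial$config$leg_length
    if (!is.null(trial$participant)) participant <- trial$participant
    if (!is.null(trial$leg_length)) leg_length <- trial$leg_length
  } else {
    signals <- trial
  }
  stopifnot(is.data.frame(signals), !is.null(fs), !is.null(condition))
  missing_cols <- setdiff(trial_required_columns, names(signals))
  if (length(missing_cols)) {
    stop("signals are missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# gaitfpe_trial v1",
    sprintf("# fs_hz: %s", format(fs, digits = 17)),
    sprintf("# condition: %s", condition),
    sprintf("# participant: %s", participant),
    sprintf("# leg_length_m: %s", format(leg_length, digits = 17))
  ), con)
  writeLines(paste(names(signals), collapse = ","), con)
  cols <- lapply(signals, function(x) sprintf("%.17g", x))
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

#' Read a gait trial file
#'
#' Parses the metadata header and the CSV body, validates that all required
#' channels are present (by their unit-suffixed names), that the time column
#' is strictly increasing and uniform to within 1e-6 s, and that it agrees
#' with the header sampling rate. Malformed files are rejected with
#' diagnostics naming the offending column or line.
#'
#' @param path file written by [write_trial()].
#' @return an object of class `gait_trial`: list with `signals`, `fs`,
#'   `condition`, `participant`, `leg_length`.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, n = 64L)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  fs <- suppressWarnings(as.numeric(get_meta("fs_hz")))
  if (!is.finite(fs) || fs <= 0) {
    stop("trial header lacks a valid `fs_hz` entry", call. = FALSE)
  }
  condition <- get_meta("condition")
  participant <- get_meta("participant")
  leg_length <- suppressWarnings(as.numeric(get_meta("leg_length_m")))
  signals <- utils::read.csv(path, comment.char = "#",
                             colClasses = "numeric")
  missing_cols <- setdiff(trial_required_columns, names(signals))
  if (length(missing_cols)) {
    stop("trial file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (nm in names(signals)) {
    if (anyNA(signals[[nm]])) {
      stop("non-numeric or missing value in column `", nm, "` near line ",
           which(is.na(signals[[nm]]))[1] + length(hdr) + 1L, call. = FALSE)
    }
  }
  dt <- diff(signals$time_s)
  if (any(dt <= 0)) {
    stop("`time_s` is not strictly increasing at row ",
         which(dt <= 0)[1] + 1L, call. = FALSE)
  }
  if (max(abs(dt - 1 / fs)) > 1e-6) {
    stop("`time_s` spacing disagrees with header fs_hz = ", fs,
         " by more than 1e-6 s", call. = FALSE)
  }
  structure(list(signals = signals, fs = fs, condition = condition,
                 participant = participant, leg_length = leg_length),
            class = "gait_trial")
}

#' Write the ground-truth sidecar of a synthetic trial
#'
#' JSON with events (samples and seconds, per side), foot placement errors
#' (m), foot placement, and heel-strike CoM states.
#'
#' @param trial a `synthetic_trial`.
#' @param path output path (.json).
#' @return `path`, invisibly.
#' @export
write_truth <- function(trial, path) {
  stopifnot(inherits(trial, "synthetic_trial"))
  ev <- trial$truth$events
  ev_json <- lapply(c("left", "right"), function(sd) {
    list(
      heel_strikes = list(sample = ev$heel_strikes[[sd]],
                          time_s = (ev$heel_strikes[[sd]] - 1) / ev$fs),
      toe_offs = list(sample = ev$toe_offs[[sd]],
                      time_s = (ev$toe_offs[[sd]] - 1) / ev$fs))
  })
  names(ev_json) <- c("left", "right")
  jsonlite::write_json(list(
    events = ev_json,
    fp_errors_m = trial$truth$fp_errors,
    fp_dev_m = trial$truth$fp_dev,
    fp_raw_m = trial$truth$fp_raw,
    com_states = trial$truth$states,
    condition = trial$condition,
    seed = trial$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the knobs of the full analysis: event detection parameters, the
#' per-condition phase grids, the extreme-contrast size, and the inference
#' settings.
#'
#' @param J_ds,J_ss phase-grid sizes; `NULL` picks the per-condition default
#'   (20/80 normal, 25/75 slow).
#' @param alpha significance level for all tests.
#' @param n_permutations sign-flip permutations for cluster inference.
#' @param k steps per tail of the extreme-error contrast.
#' @param min_step_time,smooth_window event-detector parameters (s).
#' @param method interpolation method for time normalization.
#' @param seed RNG seed for the permutation tests.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(J_ds = NULL, J_ss = NULL, alpha = 0.05,
                            n_permutations = 10000, k = 10,
                            min_step_time = 0.3, smooth_window = 0.03,
                            method = "linear", seed = 1L) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  structure(list(J_ds = J_ds, J_ss = J_ss, alpha = alpha,
                 n_permutations = n_permutations, k = k,
                 min_step_time = min_step_time,
                 smooth_window = smooth_window, method = method,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

grid_for_condition <- function(config, condition) {
  defaults <- if (identical(condition, "slow")) c(25L, 75L) else c(20L, 80L)
  c(if (is.null(config$J_ds)) defaults[1] else config$J_ds,
    if (is.null(config$J_ss)) defaults[2] else config$J_ss)
}

# Run all per-trial stages; stage failures are re-raised with the stage name
# and trial id.
analyze_trial <- function(trial, config, id = "trial") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed for trial '", id, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  grid <- grid_for_condition(config, trial$condition)
  events <- stage("detect_events", detect_events_from_cop(
    trial$signals$cop_ap_m, trial$signals$cop_ml_m, trial$fs,
    min_step_time = config$min_step_time,
    smooth_window = config$smooth_window))
  steps <- stage("segment_steps", segment_steps(events))
  sm <- stage("time_normalize", time_normalize(
    trial$signals, steps, J_ds = grid[1], J_ss = grid[2],
    method = config$method))
  fpm <- stage("foot_placement_model", fit_fpm_by_side(sm))
  channels <- stage("kinetic_channels", kinetic_channels(sm))
  signals <- c("combined_ap_grf", "trailing_ap_grf", "trailing_ankle_moment")
  fields <- list()
  for (sig in signals) {
    per_side <- list()
    for (sd in unique(sm$meta$side)) {
      sel <- which(sm$meta$side == sd)
      per_side[[sd]] <- stage(paste0("correlate_", sig),
        pushoff_correlation_field(fpm$errors, channels, signal = sig,
                                  J_ds = sm$J_ds, subset = sel))
    }
    fields[[sig]] <- per_side
  }
  contrasts <- lapply(signals, function(sig) {
    Y <- cbind(channels[[sig]]$same_step[-nrow(sm$meta), , drop = FALSE],
               channels[[sig]]$next_step[-1L, , drop = FALSE])
    err <- fpm$errors[-nrow(sm$meta)]
    if (sum(is.finite(err)) >= 2 * config$k) {
      extreme_error_contrast(err, Y, k = config$k, lag = "aligned")
    } else NULL
  })
  names(contrasts) <- signals
  list(events = events, stride_matrix = sm, fpm = fpm, fields = fields,
       contrasts = contrasts, condition = trial$condition, id = id)
}

# z-space average of a participant's per-foot correlation curves.
participant_curve <- function(per_side_fields) {
  rmats <- do.call(rbind, lapply(per_side_fields, function(f) f$r))
  fisher_mean(pmin(pmax(rmats, -1 + 1e-12), 1 - 1e-12), na.rm = FALSE)
}

#' Run the full analysis pipeline over a set of trials
#'
#' For every trial: event detection from the CoP, step segmentation,
#' two-window time normalization, the per-foot foot placement model, and
#' per-foot error-kinetics correlation fields for the three kinetic signals
#' plus the extreme-error contrast. Trials are then grouped by condition;
#' per participant the two per-foot fields are averaged in Fisher-z space,
#' and each condition x signal group field is tested with permutation
#' cluster inference. Results and a machine-readable manifest are optionally
#' written to `out_dir`.
#'
#' @param trials list of `gait_trial` / `synthetic_trial` objects, or a
#'   character vector of file paths readable by [read_trial()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `per_trial` results, `group` (per condition, per
#'   signal: a [group_correlation_field()]), and `manifest`.
#' @export
run_pipeline <- function(trials, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(trials)) {
    ids <- basename(trials)
    trials <- lapply(trials, read_trial)
  } else {
    ids <- vapply(seq_along(trials), function(i) {
      p <- trials[[i]]$participant
      if (is.null(p) || is.na(p)) sprintf("trial%02d", i) else p
    }, character(1))
  }
  if (length(trials) < 1) stop("need at least one trial", call. = FALSE)
  per_trial <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    per_trial[[i]] <- analyze_trial(trials[[i]], config, id = ids[i])
  }
  signals <- c("combined_ap_grf", "trailing_ap_grf", "trailing_ankle_moment")
  conditions <- unique(vapply(per_trial, `[[`, character(1), "condition"))
  group <- list()
  for (cond in conditions) {
    sel <- which(vapply(per_trial, `[[`, character(1), "condition") == cond)
    group[[cond]] <- list()
    for (sig in signals) {
      curves <- do.call(rbind, lapply(per_trial[sel], function(res) {
        participant_curve(res$fields[[sig]])
      }))
      group[[cond]][[sig]] <- if (nrow(curves) >= 3) {
        group_correlation_field(curves,
                                phase = per_trial[[sel[1]]]$fields[[sig]][[1]]$phase,
                                alpha = config$alpha,
                                n_permutations = config$n_permutations,
                                seed = config$seed)
      } else NULL
    }
  }
  manifest <- list(
    package = "gaitfpe",
    version = as.character(utils::packageVersion("gaitfpe")),
    config = unclass(config),
    n_trials = length(trials),
    trial_ids = ids,
    conditions = conditions
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cond in conditions) {
      for (sig in signals) {
        gf <- group[[cond]][[sig]]
        if (is.null(gf)) next
        base <- file.path(out_dir, paste0("group_", cond, "_", sig))
        utils::write.csv(data.frame(phase = gf$phase, mean_r = gf$mean_r),
                         paste0(base, ".csv"), row.names = FALSE)
        cl <- gf$clusters
        report <- if (nrow(cl) == 0) "no supra-threshold clusters" else
          sprintf("cluster [%g%%, %g%%] stat %.3f p = %.4f%s",
                  cl$phase_start, cl$phase_end, cl$stat, cl$p_value,
                  ifelse(cl$significant, " *", ""))
        writeLines(report, paste0(base, "_clusters.txt"))
      }
    }
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
    written <- list.files(out_dir, full.names = TRUE)
    manifest$file_md5 <- as.list(tools::md5sum(written))
  }
  list(per_trial = per_trial, group = group, manifest = manifest)
}
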
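test_that("trial files round-trip bit-identically", {
  tr <- simulate_trial(small_config(), seed = 80)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, path, participant = "S01")
  back <- read_trial(path)
  expect_identical(back$signals$com_pos_ap_m, tr$signals$com_pos_ap_m)
  expect_identical(back$signals$grf_ap_left_N, tr$signals$grf_ap_left_N)
  expect_equal(back$fs, tr$fs)
  expect_equal(back$condition, tr$condition)
  expect_equal(back$participant, "S01")
  expect_equal(back$leg_length, 0.9)
})

test_that("a missing required column is rejected by name", {
  tr <- simulate_trial(small_config(), seed = 81)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, path)
  lines <- readLines(path)
  lines[6] <- sub("ankle_moment_left_Nm", "ankle_left", lines[6])
  writeLines(lines, path)
  expect_error(read_trial(path), "ankle_moment_left_Nm")
})

test_that("a sampling-rate mismatch beyond 1e-6 s is rejected", {
  tr <- simulate_trial(small_config(), seed = 82)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, path)
  lines <- readLines(path)
  lines[2] <- "# fs_hz: 201"
  writeLines(lines, path)
  expect_error(read_trial(path), "fs_hz")
})

test_that("truth sidecars serialize events in samples and seconds", {
  tr <- simulate_trial(small_config(), seed = 83)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(tr, path)
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(truth$events$left$heel_strikes$sample,
               tr$truth$events$heel_strikes$left)
  expect_equal(truth$events$left$heel_strikes$time_s,
               (tr$truth$events$heel_strikes$left - 1) / tr$fs)
  expect_equal(truth$fp_errors_m, tr$truth$fp_errors, tolerance = 1e-12)
})

test_that("pipeline configuration validates and loads from yaml", {
  expect_error(pipeline_config(alpha = 1.2), "alpha")
  expect_error(pipeline_config(k = 0), "k")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("alpha: 0.01", "k: 5", "n_permutations: 500", "seed: 42"),
             path)
  cfg <- pipeline_config_from_yaml(path)
  expect_equal(cfg$alpha, 0.01)
  expect_equal(cfg$k, 5)
  expect_equal(cfg$seed, 42L)
})

test_that("the pipeline produces one group field per signal and condition", {
  trials <- lapply(1:3, function(i) {
    tr <- simulate_trial(gait_config(n_strides = 40, seed = 90 + i))
    tr$participant <- sprintf("P%02d", i)
    tr
  })
  out_dir <- withr::local_tempdir()
  res <- run_pipeline(trials,
                      pipeline_config(k = 5, n_permutations = 200,
                                      seed = 7),
                      out_dir = out_dir)
  expect_length(res$per_trial, 3)
  expect_named(res$group, "normal")
  expect_setequal(names(res$group$normal),
                  c("combined_ap_grf", "trailing_ap_grf",
                    "trailing_ankle_moment"))
  for (sig in names(res$group$normal)) {
    expect_s3_class(res$group$normal[[sig]], "group_field")
  }
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  expect_true(file.exists(file.path(out_dir,
                                    "group_normal_trailing_ap_grf.csv")))
  # per-trial results carry fits, fields and contrasts
  pt <- res$per_trial[[1]]
  expect_s3_class(pt$fpm$fits$left, "fpm_fit")
  expect_s3_class(pt$fields$trailing_ap_grf$left, "correlation_field")
  expect_s3_class(pt$contrasts$trailing_ap_grf, "extreme_contrast")
})

test_that("reruns with the same seeds are reproducible", {
  trials <- lapply(1:3, function(i) {
    simulate_trial(gait_config(n_strides = 30, seed = 100 + i))
  })
  cfg <- pipeline_config(k = 3, n_permutations = 200, seed = 11)
  r1 <- run_pipeline(trials, cfg)
  r2 <- run_pipeline(trials, cfg)
  expect_identical(
    r1$group$normal$trailing_ap_grf$clusters,
    r2$group$normal$trailing_ap_grf$clusters)
  expect_identical(r1$group$normal$combined_ap_grf$mean_r,
                   r2$group$normal$combined_ap_grf$mean_r)
})

test_that("a corrupted trial aborts with the stage and trial named", {
  tr_ok <- simulate_trial(gait_config(n_strides = 30, seed = 104))
  tr_bad <- tr_ok
  tr_bad$signals$cop_ml_m <- rep(0.02, nrow(tr_bad$signals))
  tr_bad$participant <- "BAD01"
  expect_error(
    run_pipeline(list(tr_ok, tr_bad),
                 pipeline_config(n_permutations = 200, seed = 1)),
    "detect_events.*BAD01")
})
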
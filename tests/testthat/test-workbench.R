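test_that("dataset files round-trip bit-for-bit and validate their schema", {
  cohort <- make_cohort(2, 15, master_seed = 5)
  f <- withr::local_tempfile(fileext = ".rds")
  write_dataset(cohort, f)
  back <- read_dataset(f)
  expect_identical(back, cohort)

  broken <- cohort
  broken$subjects[[1]]$rf <- NULL
  f2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(broken, f2)
  expect_error(read_dataset(f2), "subject_1/rf")

  broken2 <- cohort
  broken2$subjects[[2]]$annotation$center <- NULL
  f3 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(broken2, f3)
  expect_error(read_dataset(f3), "subject_2/annotation/center")
})

test_that("run configurations survive a YAML round-trip", {
  cfg <- run_config(n_subjects = 3L, frames_per_subject = 120L, seed = 99L,
                    roi = roi_config(pool_window = 21L),
                    smoother = smoother_config("moving_average"))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  back <- read_run_config(f)
  expect_equal(back, cfg)
})

test_that("run_pipeline writes a replayable report directory", {
  cfg <- run_config(n_subjects = 2L, frames_per_subject = 60L, seed = 4L,
                    roi_epochs = 1L, tracker_epochs = 1L,
                    roi_batch_size = 32L, tracker_batch_size = 32L)
  out <- withr::local_tempdir()
  res <- run_pipeline(cfg, out)
  expect_s3_class(res, "loso_result")
  metrics <- read.csv(file.path(out, "metrics.csv"))
  expect_identical(nrow(metrics), 3L)            # 2 folds + mean row
  expect_true(all(c("subject", "pearson_r", "rmse", "lumen_mae") %in%
                    names(metrics)))
  expect_true(file.exists(file.path(out, "config.json")))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(manifest$seed, 4L)
  expect_identical(manifest$n_folds, 2L)
  expect_true(all(c("fold_1.rds", "fold_2.rds") %in%
                    unlist(manifest$outputs)))
  expect_true(file.exists(file.path(out, "checkpoints", "fold_1.rds")))
})
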
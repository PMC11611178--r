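test_that("fits, metrics and LOSO results expose tidy/glance/autoplot surfaces", {
  r <- clean_recording(20, seed = 51)
  labels <- response_matrix(r$annotation, 1020)
  fit <- train_roi(r$env, labels, epochs = 2, batch_size = 8,
                   val_fraction = 0.2, seed = 1)

  h <- tidy(fit)
  expect_s3_class(h, "tbl_df")
  expect_named(h, c("epoch", "train_loss", "val_loss"))
  g <- glance(fit)
  expect_identical(g$n_parameters, 1210L)
  expect_identical(g$epochs, 2L)

  m <- compute_metrics(rnorm(20, 300), rnorm(20, 300))
  tm <- tidy(m)
  expect_named(tm, c("metric", "value"))
  expect_true("ccc" %in% tm$metric)
  expect_false(inherits(glance(m), "metrics_report"))

  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  tr <- lumentrack:::new_diameter_trace(rnorm(50) + 300, frame_rate = 500)
  expect_s3_class(autoplot(tr, reference = rnorm(50) + 300), "ggplot")
  expect_s3_class(autoplot(r$record, max_frames = 10), "ggplot")
})
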
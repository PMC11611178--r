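test_that("architecture contracts are enforced", {
  expect_error(tracker_config(conv_channels = c(8, 16, 32, 16)), "5 conv")
  expect_error(tracker_config(fc_widths = c(300, 64, 2)), "3 FC")
  expect_error(tracker_config(conv_channels = c(8, 32, 16, 32, 8)), "rise")
  expect_error(tracker_config(huber_delta = 0), "huber_delta")
})

test_that("parameter counts match the closed-form layer arithmetic", {
  cfg <- tracker_config()
  # conv: per layer k*ci*co weights + co bias + 2*co batch-norm
  conv <- 9 * (1 * 8 + 8 * 16 + 16 * 32 + 32 * 16 + 16 * 8) +
    3 * (8 + 16 + 32 + 16 + 8)
  fc <- (8 * 401) * 300 + 300 + 300 * 64 + 64 + 64 * 1 + 1
  expect_identical(n_parameters(cfg), as.integer(conv + fc))
  # fit object agrees with the config count
  p <- lumentrack:::tracker_init_params(cfg)
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  expect_identical(as.integer(cnt(p$conv) + cnt(p$fc)), n_parameters(cfg))
})

test_that("huber loss has the stated quadratic and linear branches", {
  expect_equal(huber_loss(5, 5, 1), 0)
  expect_equal(huber_loss(0.5, 0, 1), 0.125)
  expect_equal(huber_loss(3, 0, 1), 2.5)
  expect_equal(huber_loss(c(0.5, 3), c(0, 0), 1), mean(c(0.125, 2.5)))
  expect_error(huber_loss(1, 1, 0), "> 0")
})

test_that("inference is deterministic, bounded, and rejects width mismatches", {
  cfg <- tracker_config()
  set.seed(2)
  fit <- list(params = lumentrack:::tracker_init_params(cfg),
              running = lumentrack:::tracker_init_running(cfg),
              config = cfg)
  x <- matrix(abs(rnorm(401 * 5)), 401, 5)
  p1 <- tracker_forward(x, fit)
  p2 <- tracker_forward(x, fit)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 401))
  expect_error(tracker_forward(matrix(0, 100, 2), fit), "width")
})

test_that("the tracker overfits a small clean recording", {
  r <- clean_recording(50, seed = 41)
  fit <- train_tracker(r$env, r$annotation, epochs = 50, batch_size = 10,
                       config = tracker_config(dropout = 0), jitter = 0,
                       val_fraction = 0, seed = 5)
  h <- fit$history$train_loss
  expect_lt(h[length(h)], 0.01 * h[1])
})

test_that("tracker training is deterministic given the seed", {
  r <- clean_recording(20, seed = 43)
  f1 <- train_tracker(r$env, r$annotation, epochs = 2, batch_size = 10,
                      val_fraction = 0, seed = 9)
  f2 <- train_tracker(r$env, r$annotation, epochs = 2, batch_size = 10,
                      val_fraction = 0, seed = 9)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$running, f2$running)
})

test_that("predicted traces are per-frame, stateless, and the right length", {
  r <- clean_recording(30, seed = 44)
  labels <- response_matrix(r$annotation, 1020)
  roi_fit <- train_roi(r$env, labels, epochs = 2, batch_size = 8,
                       val_fraction = 0, seed = 1)
  trk_fit <- train_tracker(r$env, r$annotation, epochs = 2, batch_size = 8,
                           val_fraction = 0, seed = 2)
  tr <- predict_trace(r$env, roi_fit, trk_fit)
  expect_s3_class(tr, "diameter_trace")
  expect_identical(nrow(tr), 30L)
  expect_true(all(tr$diameter > 0 & tr$diameter < 1020))

  perm <- sample(30)
  tr_perm <- predict_trace(r$env[, perm], roi_fit, trk_fit)
  expect_equal(tr_perm$diameter, tr$diameter[perm], tolerance = 1e-6)
})

test_that("a trained tracker recovers clean diameters from true centers", {
  r <- clean_recording(60, seed = 45)
  fit <- train_tracker(r$env, r$annotation, epochs = 30, batch_size = 16,
                       config = tracker_config(dropout = 0), jitter = 2,
                       val_fraction = 0, seed = 6)
  w <- lumentrack:::clip_roi_batch(r$env, r$annotation$center, 401)
  pred <- tracker_forward(w, fit)
  expect_lt(mean(abs(pred - r$annotation$diameter)), 5)
})
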
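test_that("the default ROI detector has exactly 1210 trainable parameters", {
  expect_identical(n_parameters(roi_config()), 1210L)
  # and a fit object counts the same scalars
  cfg <- tiny_roi_config()
  p <- lumentrack:::roi_init_params(cfg)
  expect_identical(sum(lengths(p)), n_parameters(cfg))
})

test_that("zero input with zero biases gives all-zero maps of input length", {
  cfg <- tiny_roi_config()
  params <- list(W1 = matrix(0.3, cfg$kernel_width, cfg$channels),
                 b1 = numeric(3), w2 = c(1, 1, 1), b2 = 0)
  out <- roi_forward(numeric(120), params, cfg)
  expect_equal(out$pre, numeric(120))
  expect_equal(out$pooled, numeric(120))
})

test_that("forward pass matches a brute-force convolution oracle", {
  cfg <- tiny_roi_config()
  set.seed(4)
  params <- lumentrack:::roi_init_params(cfg)
  x <- abs(rnorm(120))
  out <- roi_forward(x, params, cfg)
  expect_length(out$pre, 120)
  expect_length(out$pooled, 120)

  # oracle: padded convolution + relu + channel combine + box average
  k <- cfg$kernel_width; half <- (k - 1) / 2
  xp <- c(numeric(half), x, numeric(half))
  pre_oracle <- vapply(seq_len(120), function(i) {
    h <- vapply(seq_len(cfg$channels), function(c) {
      max(sum(xp[i:(i + k - 1)] * params$W1[, c]) + params$b1[c], 0)
    }, numeric(1))
    sum(h * params$w2) + params$b2
  }, numeric(1))
  expect_equal(out$pre, pre_oracle, tolerance = 1e-5)

  pw <- cfg$pool_window; ph <- (pw - 1) / 2
  pp <- c(numeric(ph), pre_oracle, numeric(ph))
  pooled_oracle <- vapply(seq_len(120), function(i) {
    mean(pp[i:(i + pw - 1)])
  }, numeric(1))
  expect_equal(out$pooled, pooled_oracle, tolerance = 1e-5)
})

test_that("hand-set tent kernels turn an impulse into a pooled peak at the impulse", {
  cfg <- tiny_roi_config()
  # triangular (tent) kernel: response to an impulse peaks exactly where
  # the impulse sits (a box kernel would give a flat plateau with an
  # ambiguous argmax)
  half <- (cfg$kernel_width - 1) / 2
  tent <- 1 - abs(seq(-half, half)) / (half + 1)
  params <- list(W1 = matrix(tent, cfg$kernel_width, cfg$channels),
                 b1 = numeric(3), w2 = c(1, 1, 1), b2 = 0)
  x <- numeric(120); x[61] <- 1
  out <- roi_forward(x, params, cfg)
  expect_lte(abs(locate_lumen(out$pooled) - 60), cfg$pool_window / 2)
})

test_that("locate_lumen is an argmax with first-index ties and decimation mapping", {
  expect_identical(locate_lumen(c(0, 0.2, 0.9, 0.2)), 2L)
  expect_identical(locate_lumen(rep(1, 10)), 0L)
  for (s in 1:25) {
    set.seed(s)
    m <- rnorm(200)
    expect_identical(locate_lumen(m), which.max(m) - 1L)
  }
  expect_equal(locate_lumen(c(0, 1, 0), decimation = 4), 1 * 4 + 2)
  m <- cbind(c(0, 1, 0), c(1, 0, 0))
  expect_equal(locate_lumen(m), c(1L, 0L))
})

test_that("ROI clipping is centered and clamps at the edges", {
  env <- rnorm(1020)
  w1 <- clip_roi(env, 500, 401)
  expect_identical(w1$start, 300)
  expect_identical(w1$values, env[301:701])
  expect_identical(clip_roi(env, 50, 401)$start, 0)
  expect_identical(clip_roi(env, 1010, 401)$start, 619)
  expect_error(clip_roi(rnorm(100), 50, 401), "exceeds")
})

test_that("ROI training overfits a small clean set and is seed-deterministic", {
  r <- clean_recording(12, seed = 21)
  labels <- response_matrix(r$annotation, 1020)
  fit1 <- train_roi(r$env, labels, epochs = 5, batch_size = 4,
                    augment_shift = 0, artifact_prob = 0,
                    val_fraction = 0, seed = 7)
  expect_true(all(diff(fit1$history$train_loss) < 0))
  fit2 <- train_roi(r$env, labels, epochs = 5, batch_size = 4,
                    augment_shift = 0, artifact_prob = 0,
                    val_fraction = 0, seed = 7)
  expect_identical(fit1$params, fit2$params)
  fit3 <- train_roi(r$env, labels, epochs = 5, batch_size = 4,
                    augment_shift = 0, artifact_prob = 0,
                    val_fraction = 0, seed = 8)
  expect_false(identical(fit1$params$W1, fit3$params$W1))
})

test_that("a trained detector localizes held-out clean frames", {
  train <- clean_recording(60, seed = 31)
  test <- clean_recording(30, seed = 32)
  labels <- response_matrix(train$annotation, 1020)
  fit <- train_roi(train$env, labels, epochs = 6, batch_size = 16,
                   val_fraction = 0, seed = 3)
  centers <- predict(fit, test$env)
  expect_lt(mean(abs(centers - test$annotation$center)), 20)
})

test_that("empty training sets abort", {
  expect_error(train_roi(matrix(0, 1020, 0), matrix(0, 1020, 0)), "empty")
})
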
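test_that("savitzky-golay smoothing reproduces low-order polynomials exactly", {
  x <- seq(0, 1, length.out = 200)
  for (deg in c(2, 5)) {
    p <- 3 - 2 * x + 0.5 * x^deg + x^max(deg - 2, 1)
    sm <- smooth_trace(p, smoother_config("savitzky_golay", 31, 5))
    interior <- 16:185
    expect_equal(sm[interior], p[interior], tolerance = 1e-10)
  }
})

test_that("both smoothers leave a constant trace unchanged", {
  x <- rep(304.3, 100)
  expect_equal(smooth_trace(x, smoother_config("savitzky_golay")), x)
  expect_equal(smooth_trace(x, smoother_config("moving_average")), x)
})

test_that("smoothing reduces white-noise variance", {
  set.seed(77)
  x <- rnorm(2000)
  sg <- smooth_trace(x, smoother_config("savitzky_golay"))
  ma <- smooth_trace(x, smoother_config("moving_average"))
  expect_lt(var(sg), var(x))
  expect_lt(var(ma), var(sg))   # heavier smoothing for the same window
})

test_that("smoother contracts: window parity, order bound, length check", {
  expect_error(smoother_config(window = 30), "window")
  expect_error(smoother_config(order = 31), "order")
  expect_error(smooth_trace(rnorm(10), smoother_config()), "shorter")
  tr <- lumentrack:::new_diameter_trace(rnorm(100) + 300)
  sm <- smooth_trace(tr)
  expect_true(attr(sm, "smoothed"))
  expect_identical(nrow(sm), 100L)
})

# independent oracle: every metric recomputed from first principles
naive_metrics <- function(pred, ref) {
  n <- length(pred)
  mx <- sum(pred) / n; my <- sum(ref) / n
  sxy <- sum((pred - mx) * (ref - my))
  sx <- sqrt(sum((pred - mx)^2)); sy <- sqrt(sum((ref - my)^2))
  r <- sxy / (sx * sy)
  e <- pred - ref
  me <- sum(e) / n
  m2 <- sum((e - me)^2) / n
  list(pearson_r = r,
       r_squared = 1 - sum(e^2) / sum((ref - my)^2),
       ccc = 2 * (sxy / n) / (sum((pred - mx)^2) / n +
                                sum((ref - my)^2) / n + (mx - my)^2),
       mae = sum(abs(e)) / n,
       mse = sum(e^2) / n,
       rmse = sqrt(sum(e^2) / n),
       mad_median = median(abs(e)),
       mad_mean = sum(abs(e)) / n,
       t_value = r * sqrt((n - 2) / (1 - r^2)),
       skewness = (sum((e - me)^3) / n) / m2^1.5,
       excess_kurtosis = (sum((e - me)^4) / n) / m2^2 - 3,
       n = n)
}

test_that("compute_metrics matches the brute-force oracle to 1e-10", {
  for (s in 1:10) {
    set.seed(s)
    ref <- rnorm(50, 300, 5)
    pred <- ref + rnorm(50, 0.5, 2)
    got <- compute_metrics(pred, ref)
    want <- naive_metrics(pred, ref)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10, label = f)
    }
  }
})

test_that("perfect agreement and constant offsets behave as expected", {
  x <- rnorm(40, 300, 4)
  m <- compute_metrics(x, x)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$r_squared, 1)
  expect_equal(m$ccc, 1)
  expect_equal(m$mae + m$mse + m$rmse + m$mad_median, 0)

  mo <- compute_metrics(x + 3, x)
  expect_equal(mo$pearson_r, 1)
  expect_lt(mo$ccc, 1)
  expect_equal(mo$mae, 3)
  expect_equal(mo$r_squared, 1 - 9 * 40 / sum((x - mean(x))^2))
})

test_that("metric invariants hold on random data", {
  for (s in 1:5) {
    set.seed(s + 100)
    ref <- rnorm(60, 300, 6)
    pred <- 0.9 * ref + rnorm(60, 5, 3)
    m <- compute_metrics(pred, ref)
    expect_lte(abs(m$pearson_r), 1)
    expect_lte(abs(m$ccc), abs(m$pearson_r) + 1e-12)
    expect_equal(m$rmse, sqrt(m$mse))
  }
})

test_that("degenerate metric inputs are rejected", {
  expect_error(compute_metrics(1:5, 1:4), "equal length")
  expect_error(compute_metrics(c(1, 2), c(1, 2)), "at least 3")
  expect_error(compute_metrics(rnorm(10), rep(1, 10)), "constant")
})

test_that("sample-to-mm conversion uses the acquisition depth scale", {
  expect_equal(samples_to_mm(0), 0)
  expect_equal(samples_to_mm(1000, 24.65), 24.65)
  expect_equal(samples_to_mm(6.4724), 0.15954, tolerance = 1e-4)
})

test_that("LOSO bookkeeping: one fold per subject, mean row is the column mean", {
  cohort <- make_cohort(2, 70, master_seed = 13)
  res <- loso_evaluate(cohort, roi_epochs = 1, tracker_epochs = 1, seed = 3,
                       roi_args = list(batch_size = 32),
                       tracker_args = list(batch_size = 32))
  expect_identical(nrow(res$folds), 2L)
  expect_identical(res$folds$subject, c("subject_1", "subject_2"))
  expect_identical(res$folds$n_train_frames, c(70L, 70L))
  expect_equal(res$summary$pearson_r, mean(res$folds$pearson_r))
  expect_equal(res$summary$rmse, mean(res$folds$rmse))
  expect_identical(res$summary$subject, "mean")
})
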
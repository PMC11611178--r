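test_that("envelope of the zero frame is zero and of a pure tone is its amplitude", {
  expect_equal(hilbert_envelope(numeric(64)), numeric(64))
  n <- 0:255
  env <- hilbert_envelope(3 * cos(2 * pi * 0.25 * n))
  interior <- 11:245
  expect_equal(env[interior], rep(3, length(interior)), tolerance = 0.01)
})

test_that("envelope of a Gabor pulse recovers its Gaussian envelope", {
  n <- seq(-100, 100)
  sigma <- 4
  x <- exp(-n^2 / (2 * sigma^2)) * cos(2 * pi * 0.25 * n)
  env <- hilbert_envelope(x)
  gauss <- exp(-n^2 / (2 * sigma^2))
  core <- abs(n) <= 8   # where the pulse is not vanishingly small
  expect_lt(max(abs(env[core] - gauss[core]) / gauss[core]), 0.05)
})

test_that("envelope is positively homogeneous", {
  set.seed(1)
  x <- rnorm(128)
  expect_equal(hilbert_envelope(2.5 * x), 2.5 * hilbert_envelope(x),
               tolerance = 1e-12)
})

test_that("non-finite frames are rejected with the frame index", {
  expect_error(hilbert_envelope(c(1, NA, rep(0, 10))), "non-finite")
  r <- clean_recording(3)
  r$record$samples[5, 2] <- Inf
  expect_error(envelope_record(r$record), "frame 2")
})

test_that("depth decimation keeps block maxima and maps indices back", {
  expect_identical(decimate_depth(c(0, 1, 0, 0, 5, 0, 0, 0), 4), c(1, 5))
  x <- rnorm(16)
  expect_identical(decimate_depth(x, 1), x)
  # block-max composition: (a then b) == (a*b)
  set.seed(2)
  y <- abs(rnorm(120))
  expect_equal(decimate_depth(decimate_depth(y, 2), 3), decimate_depth(y, 6))
  # argmax survives decimation to within half a block
  for (s in 1:20) {
    set.seed(s)
    f <- abs(rnorm(240))
    dec <- decimate_depth(f, 8)
    mapped <- (which.max(dec) - 1) * 8 + 4
    expect_lte(abs(mapped - (which.max(f) - 1)), 4)
  }
})

test_that("non-divisor decimation factors are refused with a suggestion", {
  expect_error(decimate_depth(rnorm(100), 7), "nearest valid factor")
})

test_that("per-frame normalization scales the peak to one and keeps the argmax", {
  expect_equal(normalize_frame(c(2, 4, 8)), c(0.25, 0.5, 1))
  x <- abs(rnorm(50)) + 0.1
  expect_equal(normalize_frame(normalize_frame(x)), normalize_frame(x))
  for (s in 1:10) {
    set.seed(s)
    f <- abs(rnorm(64)) + 0.01
    expect_identical(which.max(normalize_frame(f)), which.max(f))
  }
  expect_error(normalize_frame(numeric(10)), "zero")
})

test_that("envelope_record produces a normalized envelope stack", {
  r <- clean_recording(8)
  env <- envelope_record(r$record)
  expect_s3_class(env, "mmode_record")
  expect_identical(env$kind, "envelope")
  expect_identical(dim(env$samples), dim(r$record$samples))
  expect_true(all(env$samples >= 0))
  expect_equal(unname(apply(env$samples, 2, max)), rep(1, 8))
})
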
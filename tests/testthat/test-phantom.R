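test_that("diameter waveform reduces to the mean with all modulations off", {
  cfg <- phantom_subject_config(pulse_amplitude = 0, resp_amplitude = 0,
                                trend_amplitude = 0)
  d <- diameter_waveform(cfg, 500)
  expect_equal(d, rep(7.5, 500))
})

test_that("waveform mean over whole cycles matches the quadrature of the pulse shape", {
  # independent oracle: numerically integrate the stated pulse shape
  pulse <- function(phase) {
    ifelse(phase < 0.15, 0.5 * (1 - cos(pi * phase / 0.15)),
           exp(-(phase - 0.15) / 0.25))
  }
  mean_pulse <- stats::integrate(pulse, 0, 1, subdivisions = 2000L,
                                 rel.tol = 1e-10)$value
  # 60 bpm at 500 Hz: one cardiac cycle = 500 frames; resp 7.5/min = 4000
  # frames; 8 cardiac cycles and one respiratory cycle in 4000 frames
  cfg <- phantom_subject_config(trend_amplitude = 0)
  d <- diameter_waveform(cfg, 4000)
  expect_equal(mean(d), 7.5 + 0.5 * mean_pulse, tolerance = 1e-3)
})

test_that("mean diameter converts to the expected depth-sample scale", {
  expect_equal(lumentrack:::mm_to_samples(7.5, 24.65), 304.2596,
               tolerance = 1e-4)
})

test_that("waveform is deterministic and positive", {
  cfg <- phantom_subject_config()
  expect_identical(diameter_waveform(cfg, 100), diameter_waveform(cfg, 100))
  expect_gt(min(diameter_waveform(cfg, 5000)), 0)
})

test_that("impossible amplitude combinations are rejected by name", {
  expect_error(phantom_subject_config(mean_diameter = 0.5,
                                      pulse_amplitude = 0.4,
                                      resp_amplitude = 0.2),
               "pulse_amplitude")
})

test_that("noiseless rendering puts exactly two strong echoes at the walls", {
  r <- clean_recording(10)
  env <- envelope_record(r$record, normalize = FALSE)$samples
  for (j in c(1, 5, 10)) {
    f <- env[, j]
    # interior local maxima above half the global max
    lm <- which(diff(sign(diff(f))) == -2) + 1
    lm <- lm[f[lm] > 0.5 * max(f)]
    expect_length(lm, 2)
    expect_lt(abs((lm[1] - 1) - r$annotation$anterior[j]), 1)
    expect_lt(abs((lm[2] - 1) - r$annotation$posterior[j]), 1)
  }
})

test_that("rendering is deterministic given the config seed", {
  cfg <- phantom_subject_config(seed = 42)
  a <- render_recording(cfg, 25)
  b <- render_recording(cfg, 25)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$annotation, b$annotation)
})

test_that("annotation satisfies its identities exactly", {
  r <- render_recording(phantom_subject_config(seed = 9), 200)
  ann <- r$annotation
  expect_true(all(ann$posterior > ann$anterior))
  expect_identical(ann$center, (ann$anterior + ann$posterior) / 2)
  expect_identical(ann$diameter, ann$posterior - ann$anterior)
})

test_that("rendered diameters track the closed-form waveform", {
  spec <- acquisition_spec()
  cfg <- phantom_subject_config(seed = 3)
  r <- render_recording(cfg, 400, spec)
  d_expect <- lumentrack:::mm_to_samples(diameter_waveform(cfg, 400, spec),
                                         spec$depth_scale)
  expect_lt(abs(mean(r$annotation$diameter) - mean(d_expect)), 2)
})

test_that("default phantom lumen is hypoechoic relative to the walls", {
  cfg <- phantom_subject_config(seed = 5)
  r <- render_recording(cfg, 60)
  env <- envelope_record(r$record, normalize = FALSE)$samples
  ratios <- vapply(seq_len(60), function(j) {
    ann <- r$annotation
    lo <- round(ann$center[j] - ann$diameter[j] / 4) + 1
    hi <- round(ann$center[j] + ann$diameter[j] / 4) + 1
    mean(env[lo:hi, j]) / max(env[, j])
  }, numeric(1))
  expect_lt(mean(ratios), 0.1)
})

test_that("wall excursion outside the depth range is a config error", {
  cfg <- phantom_subject_config(lumen_center_baseline = 100,
                                mean_diameter = 7.5, seed = 1)
  expect_error(render_recording(cfg, 10), "excursion")
})

test_that("cohorts are reproducible and respect the baseline range", {
  a <- make_cohort(3, 40, master_seed = 7)
  b <- make_cohort(3, 40, master_seed = 7)
  expect_identical(a, b)
  expect_length(a$subjects, 3)
  expect_true(all(vapply(a$subjects, function(s) ncol(s$rf$samples),
                         numeric(1)) == 40))
  baselines <- vapply(a$subjects, function(s) s$config$lumen_center_baseline,
                      numeric(1))
  expect_true(all(baselines >= 350 & baselines <= 650))
  c <- make_cohort(3, 40, master_seed = 8)
  expect_false(identical(a$subjects[[1]]$rf$samples,
                         c$subjects[[1]]$rf$samples))
})

test_that("a one-subject cohort is refused because LOSO needs two", {
  expect_error(make_cohort(1, 10, 1), "leave-one-subject-out")
})

test_that("acquisition spec checks its internal consistency", {
  expect_error(acquisition_spec(depth_scale = 30), "inconsistent")
  expect_error(acquisition_spec(center_frequency = 20e6), "0.5")
  expect_equal(acquisition_spec()$depth_scale, 24.65)
})
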
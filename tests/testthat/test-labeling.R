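test_that("lumen center and cut-off points follow the midpoint geometry", {
  expect_equal(lumen_center(280, 320), 300)
  expect_equal(lumen_center(300, 300), 300)
  expect_equal(lumen_center(292.5, 315.25), 303.875)
  expect_error(lumen_center(320, 280), "posterior")

  expect_equal(cutoff_points(300, 280, 320),
               c(anterior = 290, posterior = 310))
  expect_equal(cutoff_points(300, 300, 300),
               c(anterior = 300, posterior = 300))
  expect_equal(cutoff_points(303.875, 292.5, 315.25),
               c(anterior = 298.1875, posterior = 309.5625))
  expect_error(cutoff_points(300, 310, 320), "ordering")
})

test_that("response vector peaks at the center, vanishes at cut-offs, and hits 0.75 at quarter points", {
  r <- response_vector(280, 320, 1020)
  expect_equal(r[300 + 1], 1)          # 0-based index 300 = P_C
  expect_equal(r[290 + 1], 0)          # cut-off (open support)
  expect_equal(r[310 + 1], 0)
  expect_equal(r[295 + 1], 0.75)       # 1 - 25/100
  expect_equal(r[305 + 1], 0.75)
  expect_true(all(r >= 0 & r <= 1))
  expect_true(all(r[-(292:329)] == 0))
})

test_that("each half-support is a downward-opening quadratic", {
  r <- response_vector(280, 320, 1020)
  lower <- r[(291:300) + 1]
  d2 <- diff(diff(lower))
  expect_true(all(abs(d2 - d2[1]) < 1e-12))
  expect_lt(d2[1], 0)
})

test_that("asymmetric walls use the cut-off on the matching side", {
  # anterior 280, posterior 330 -> center 305, cuts 292.5 / 317.5
  r <- response_vector(280, 330, 1020)
  pc <- 305
  i <- 300
  expect_equal(r[i + 1], 1 - (i - pc)^2 / (pc - 292.5)^2)
  i <- 312
  expect_equal(r[i + 1], 1 - (i - pc)^2 / (317.5 - pc)^2)
})

test_that("response vectors are shift-equivariant", {
  base <- response_vector(280, 320, 1020)
  for (s in c(-150, -7, 13, 150)) {
    shifted <- response_vector(280 + s, 320 + s, 1020)
    expect_equal(shifted, lumentrack:::shift_zerofill(base, s))
  }
})

test_that("degenerate or out-of-range walls are rejected", {
  expect_error(response_vector(300, 300, 1020), "zero-width")
  expect_error(response_vector(-2, 300, 1020), "inside")
  expect_error(response_vector(300, 1020, 1020), "inside")
})

test_that("translation augmentation shifts signal and annotation together", {
  r <- clean_recording(3)
  f <- envelope_record(r$record, normalize = FALSE)$samples[, 1]
  ann <- as.list(r$annotation[1, ])

  same <- augment_translate(f, ann, 0)
  expect_identical(same$frame, f)
  expect_equal(same$annotation$anterior, ann$anterior)

  out <- augment_translate(f, ann, 50)
  expect_equal(out$annotation$anterior, ann$anterior + 50)
  expect_equal(out$annotation$posterior, ann$posterior + 50)
  # wall-echo peak moves by exactly the shift on a noiseless frame
  expect_equal(which.max(out$frame), which.max(f) + 50)
  # shifted response vector equals response vector of shifted annotation
  rv_shift <- lumentrack:::shift_zerofill(
    response_vector(ann$anterior, ann$posterior, length(f)), 50)
  rv_of_shifted <- response_vector(out$annotation$anterior,
                                   out$annotation$posterior, length(f))
  expect_equal(rv_of_shifted, rv_shift)

  expect_error(augment_translate(f, ann, -(ann$anterior + 1)), "outside")
})

test_that("response_matrix stacks per-frame labels", {
  r <- clean_recording(4)
  m <- response_matrix(r$annotation, 1020)
  expect_identical(dim(m), c(1020L, 4L))
  expect_equal(m[, 2], response_vector(r$annotation$anterior[2],
                                       r$annotation$posterior[2], 1020))
})
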
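test_that("normalization scales by the RIP maximum and is idempotent", {
  # global maximum 5 lies in the RIP column (largest column sum)
  x <- matrix(0.5, 4, 4)
  x[, 2] <- c(4, 5, 4.5, 4)
  m <- make_measurement(x)
  n1 <- normalize_intensities(m)
  expect_equal(max(n1$intensity[, 2]), 1.0)
  expect_equal(n1$intensity[1, 1], 0.1)
  n2 <- normalize_intensities(n1)
  expect_equal(n2$intensity, n1$intensity)
  expect_identical(vapply(n1$provenance, `[[`, "", "step"), "normalize")

  # RIP max 8, analyte 2 -> analyte 0.25
  x2 <- matrix(0, 4, 4)
  x2[, 1] <- 8
  x2[2, 3] <- 2
  expect_equal(normalize_intensities(make_measurement(x2))$intensity[2, 3],
               0.25)

  expect_error(normalize_intensities(make_measurement(matrix(0, 2, 2))),
               "no RIP")
})

test_that("locate_rip is the column-sum argmax with deterministic ties", {
  x <- matrix(0.1, 5, 6)
  x[, 4] <- 2
  expect_identical(locate_rip(make_measurement(x)), 4L)
  expect_warning(idx <- locate_rip(make_measurement(matrix(1, 3, 3))),
                 "tie")
  expect_identical(idx, 1L)
  expect_identical(locate_rip(make_measurement(matrix(1:3, 3, 1))), 1L)
})

test_that("baseline correction subtracts the per-row 25% quantile", {
  m <- make_measurement(matrix(c(0, 0, 0, 4), 1))
  expect_equal(baseline_correct_rip(m)$intensity[1, ], c(0, 0, 0, 4))
  m2 <- make_measurement(matrix(7, 1, 4))
  expect_equal(baseline_correct_rip(m2)$intensity[1, ], rep(0, 4))
  # linear-interpolation quantile of 1,2,3,4 is 1.75
  m3 <- make_measurement(matrix(1:4, 1))
  expect_equal(baseline_correct_rip(m3)$intensity[1, ],
               c(0, 0.25, 1.25, 2.25))
  # rows are corrected independently
  m4 <- make_measurement(rbind(c(1, 2, 3, 4), c(10, 10, 10, 10)))
  out <- baseline_correct_rip(m4)$intensity
  expect_equal(out[1, ], c(0, 0.25, 1.25, 2.25))
  expect_equal(out[2, ], rep(0, 4))
})

test_that("noise estimation averages the sub-0.4 IRM region", {
  x <- matrix(1, 2, 6)
  m <- make_measurement(x, irm = c(0.1, 0.2, 0.3, 0.5, 0.6, 0.7))
  x[, 1:3] <- 0.2
  expect_equal(estimate_noise(make_measurement(
    x, irm = c(0.1, 0.2, 0.3, 0.5, 0.6, 0.7)))$level, 0.2)

  x2 <- matrix(rep(c(0, 0.1, 0.2, 0.3), each = 1), 1)
  m2 <- make_measurement(x2, irm = c(0.1, 0.2, 0.3, 0.39))
  expect_equal(estimate_noise(m2)$level, 0.15)

  m3 <- make_measurement(matrix(0, 2, 2), irm = c(0.1, 0.2))
  expect_equal(estimate_noise(m3)$level, 0)

  m4 <- make_measurement(matrix(1, 2, 2), irm = c(0.5, 0.6))
  expect_error(estimate_noise(m4), "region_max_irm")
})

test_that("noise subtraction clamps at zero", {
  m <- make_measurement(matrix(c(0.05, 0.5, 0, 1), 2))
  out <- subtract_noise(m, list(level = 0.1))
  expect_equal(out$intensity, matrix(c(0, 0.4, 0, 0.9), 2))
  expect_equal(subtract_noise(m, list(level = 0))$intensity, m$intensity)
  expect_error(subtract_noise(m, list(level = -1)), "non-negative")
})

test_that("wavelet denoising preserves constants and inverts at 0 levels", {
  m <- make_measurement(matrix(3.3, 2, 64))
  expect_lt(max(abs(denoise_wavelet(m, 2)$intensity - 3.3)), 1e-9)

  vals <- mccims:::with_seed(4, matrix(stats::runif(2 * 80, 0.2, 1), 2))
  m2 <- make_measurement(vals)
  expect_lt(max(abs(denoise_wavelet(m2, 0)$intensity - vals)), 1e-9)

  expect_error(denoise_wavelet(m2, 10), "exceeds decomposition depth")
})

test_that("wavelet denoising kills high-frequency alternation, keeps peaks", {
  irm <- seq_len(128)
  smooth <- 2 * exp(-(irm - 64)^2 / (2 * 10^2)) + 0.5
  noisy <- smooth + 0.2 * rep_len(c(1, -1), 128)
  m <- make_measurement(rbind(noisy, noisy))
  out <- denoise_wavelet(m, 2)$intensity[1, ]
  resid_amp <- max(abs((out - smooth)[40:90]))
  expect_lt(resid_amp, 0.2 / 10)            # alternation reduced >= 10x
  expect_lt(abs(max(out) - max(smooth)) / max(smooth), 0.05)
})

test_that("2D filters preserve constants, shapes and axes", {
  m <- make_measurement(matrix(2, 8, 20))
  for (f in list(function(x) filter_gaussian(x, 1),
                 function(x) filter_median(x, 3),
                 function(x) filter_savgol(x, 9, 2))) {
    out <- f(m)
    expect_equal(out$intensity, m$intensity, tolerance = 1e-12)
    expect_identical(dim(out$intensity), dim(m$intensity))
    expect_identical(out$rt_axis, m$rt_axis)
  }
})

test_that("median filter removes an isolated impulse", {
  x <- matrix(0, 7, 7)
  x[4, 4] <- 5
  out <- filter_median(make_measurement(x), 3)
  expect_true(all(out$intensity == 0))
  expect_error(filter_median(make_measurement(x), 4), "odd")
})

test_that("Savitzky-Golay reproduces polynomials up to its order", {
  ramp <- matrix(seq(0.5, 2, length.out = 30), 2, 30, byrow = TRUE)
  m <- make_measurement(ramp, irm = seq(0.05, by = 0.05, length.out = 30))
  out <- filter_savgol(m, 9, 2)
  expect_lt(max(abs(out$intensity[, 5:26] - ramp[, 5:26])), 1e-9)
  expect_error(filter_savgol(m, 8, 2), "odd")
  expect_error(filter_savgol(m, 3, 2), "polyorder")
})

test_that("preprocessing invariants hold on a synthetic sample", {
  ds <- synth_preset("minimal", seed = 3)
  m <- ds$measurements[[1]]
  pre <- preprocess_default(m)
  expect_identical(dim(pre$intensity), dim(m$intensity))
  expect_true(all(pre$intensity >= 0))
  expect_identical(vapply(pre$provenance, `[[`, "", "step"),
                   c("normalize", "baseline", "subtract_noise", "gaussian"))
  # subtracting the estimated noise reduces the noise-region average
  n0 <- estimate_noise(m)
  sub <- subtract_noise(m, n0)
  expect_lte(estimate_noise(sub)$level, n0$level)
  # replaying the stored chain reproduces the preprocessed matrix
  replay <- apply_chain(ds$measurements[[2]], pre$provenance)
  direct <- preprocess_default(ds$measurements[[2]])
  expect_equal(replay$intensity, direct$intensity)
})
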
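noise_fix <- function(level) list(level = level, region_max_irm = 0.4)

test_that("all three detectors localize a single clean Gaussian apex", {
  m <- gaussian_measurement()
  apex <- matrix_apex(m)
  for (pk in list(detect_tophat(m, 0.1),
                  detect_jibb(m, noise_fix(0.01)),
                  detect_watershed(m, noise_fix(0.1)))) {
    expect_identical(nrow(pk), 1L)
    expect_equal(pk$rt, unname(apex["rt"]))
    expect_equal(pk$irm, unname(apex["irm"]))
    expect_equal(pk$intensity,
                 m$intensity[match(pk$rt, m$rt_axis),
                             match(pk$irm, m$irm_axis)])
  }
})

test_that("tophat handles thresholds, separation, and degenerate input", {
  m <- gaussian_measurement()
  expect_identical(nrow(detect_tophat(m, 2)), 0L)   # everything below thr

  # two Gaussians separated by more than the window extent -> 2 peaks
  m2 <- gaussian_measurement(rt_c = 12, irm_c = 0.3)
  m3 <- gaussian_measurement(rt_c = 38, irm_c = 0.9)
  both <- make_measurement(m2$intensity + m3$intensity,
                           rt = m2$rt_axis, irm = m2$irm_axis)
  pk <- detect_tophat(both, 0.1)
  expect_identical(nrow(pk), 2L)
  expect_equal(pk$rt, c(matrix_apex(m2)["rt"], matrix_apex(m3)["rt"]),
               ignore_attr = TRUE)
  expect_error(detect_tophat(m, 0.1, window = c(4, 5)), "odd")
  expect_error(detect_tophat(m, -1), "non-negative")
})

test_that("JIBB requires sustained monotone rises", {
  # wide clean Gaussian: exactly one peak at the apex
  m <- gaussian_measurement(rt_sigma = 5, irm_sigma = 0.08)
  pk <- detect_jibb(m, noise_fix(0.01))
  expect_identical(nrow(pk), 1L)
  expect_equal(c(pk$rt, pk$irm), unname(matrix_apex(m)))

  # plateau of equal values: non-strict rule keeps it, tie-break to the
  # smallest (rt, irm) corner of the plateau region
  x <- matrix(0, 21, 21)
  x[8:14, 8:14] <- 1
  mp <- make_measurement(x, rt = 1:21,
                         irm = seq(0.01, by = 0.01, length.out = 21))
  pkp <- detect_jibb(mp, noise_fix(0.1), rise_steps = 5)
  expect_identical(nrow(pkp), 1L)
  expect_equal(pkp$rt, 8)

  # width-1 spike: under the strict reading it lacks consecutive rises;
  # the default non-strict rule accepts it as a (noise-like) local maximum
  xs <- matrix(0, 21, 21)
  xs[11, 11] <- 1
  ms <- make_measurement(xs, rt = 1:21,
                         irm = seq(0.01, by = 0.01, length.out = 21))
  expect_identical(nrow(detect_jibb(ms, noise_fix(0.1), rise_steps = 5,
                                    strict = TRUE)), 0L)
  expect_identical(nrow(detect_jibb(ms, noise_fix(0.1), rise_steps = 5)), 1L)

  expect_error(detect_jibb(ms, noise_fix(0)), "min_threshold")
})

test_that("watershed separates saddle-joined peaks and respects the floor", {
  # heights 1.0 and 0.5 joined by a saddle ~0.2, noise floor 0.1 -> 2 peaks
  big <- gaussian_measurement(rt_c = 20, irm_c = 0.5, height = 1,
                              rt_sigma = 3, irm_sigma = 0.06)
  small <- gaussian_measurement(rt_c = 20, irm_c = 0.75, height = 0.5,
                                rt_sigma = 3, irm_sigma = 0.06)
  m <- make_measurement(big$intensity + small$intensity,
                        rt = big$rt_axis, irm = big$irm_axis)
  saddle <- min(m$intensity[which.min(abs(m$rt_axis - 20)),
                            m$irm_axis > 0.5 & m$irm_axis < 0.75])
  expect_lt(saddle, 0.5)
  pk <- detect_watershed(m, noise_fix(0.1))
  expect_identical(nrow(pk), 2L)
  expect_equal(sort(pk$irm)[1], unname(matrix_apex(big)["irm"]),
               tolerance = 0.02)

  expect_identical(nrow(detect_watershed(m, noise_fix(3))), 0L)

  # brute-force oracle: peaks are local maxima whose component at the
  # spawning level contains no earlier peak
  m1 <- gaussian_measurement()
  expect_identical(nrow(detect_watershed(m1, noise_fix(0.1))), 1L)
})

test_that("layer extraction reads rectangle maxima independently", {
  m <- gaussian_measurement(rt_c = 25, irm_c = 0.6)
  apex <- matrix_apex(m)
  layer <- data.frame(name = c("P1", "P2"),
                      rt_center = c(25, 25), irm_center = c(0.6, 0.62),
                      rt_radius = c(5, 5), irm_radius = c(0.05, 0.05))
  pk <- detect_layer(m, layer)
  expect_identical(nrow(pk), 2L)   # overlapping rectangles -> one peak each
  expect_true(all(pk$rt == apex["rt"]))
  expect_true(all(pk$irm == apex["irm"]))

  # exact-zero region (the Gaussian fixture has tiny but nonzero tails)
  mz <- m
  mz$intensity[mz$intensity < 1e-6] <- 0
  zero_layer <- data.frame(name = "Z", rt_center = 45, irm_center = 0.1,
                           rt_radius = 2, irm_radius = 0.02)
  expect_identical(nrow(detect_layer(mz, zero_layer)), 0L)

  off <- data.frame(name = "off", rt_center = 500, irm_center = 0.5,
                    rt_radius = 1, irm_radius = 0.01)
  expect_warning(pk_off <- detect_layer(m, off), "outside")
  expect_identical(nrow(pk_off), 0L)

  empty <- read_layer(textConnection(
    "name,rt_center,irm_center,rt_radius,irm_radius"))
  expect_identical(nrow(detect_layer(m, empty)), 0L)
})

test_that("detection is deterministic and reports measurement intensities", {
  ds <- synth_preset("minimal", seed = 5)
  pre <- preprocess_default(ds$measurements[[1]])
  a <- detect_peaks(pre)
  b <- detect_peaks(pre)
  expect_identical(a, b)
  for (pk in a) {
    if (!nrow(pk)) next
    ri <- match(pk$rt, pre$rt_axis)
    ci <- match(pk$irm, pre$irm_axis)
    expect_equal(pk$intensity, pre$intensity[cbind(ri, ci)])
    expect_true(all(pk$intensity > 0))
  }
})

test_that("PEAX is wrapped as an optional external tool", {
  m <- gaussian_measurement()
  err <- tryCatch(run_peax(m, NULL), error = identity)
  expect_s3_class(err, "mccims_peax_unavailable")

  out <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("measurement_name\tpeak_name\tt\tr\tsignal",
               "m1\tp1\t10.5\t0.55\t1.2",
               "m1\tp2\t20.0\t0.75\t0.8",
               "m1\tp3\t30.5\t0.95\t0.4"), out)
  pk <- parse_peax_output(out, "m1")
  expect_identical(nrow(pk), 3L)
  expect_equal(sort(pk$rt), c(10.5, 20.0, 30.5))
  expect_identical(unique(pk$method), "PEAX")

  writeLines(c("measurement_name\tpeak_name\tt\tr\tsignal",
               "m1\tp1\t10.5\tbad\t1.2"), out)
  expect_error(parse_peax_output(out, "m1"), "line 2")
})
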
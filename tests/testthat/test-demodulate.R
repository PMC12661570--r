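make_recording <- function(duration, fs = 2000) {
  n <- round(duration * fs)
  radarleak:::new_radar_recording("S1", fs, sin((1:n) / 50), cos((1:n) / 50))
}

test_that("window segmentation follows floor arithmetic and drops tails", {
  win <- segment_windows(make_recording(600), 10)
  expect_equal(nrow(win), 60)
  expect_true(all(lengths(win$i) == 20000))
  expect_equal(win$window_index, 0:59)

  win2 <- segment_windows(make_recording(615), 10)
  expect_equal(nrow(win2), 61)
  # bookkeeping: window samples + discarded tail = recording length
  expect_equal(sum(lengths(win2$i)) + 5 * 2000, 615 * 2000)

  expect_error(segment_windows(make_recording(9.5), 10), "shorter")
})

test_that("direct ellipse fit recovers generating parameters", {
  # circle case
  th <- seq(0, 2 * pi, length.out = 101)[-1]
  fc <- fit_ellipse(cos(th), sin(th))
  expect_equal(fc$center_i, 0, tolerance = 1e-10)
  expect_equal(fc$center_q, 0, tolerance = 1e-10)
  expect_equal(fc$semi_axis_major, 1, tolerance = 1e-10)
  expect_equal(fc$semi_axis_minor, 1, tolerance = 1e-10)

  # 500 noiseless points, known geometry, parameters within 1e-6
  withr::with_seed(2, {
    th <- stats::runif(500, 0, 2 * pi)
    rot <- 30 * pi / 180
    x <- 0.3 + 1.2 * cos(th) * cos(rot) - 0.8 * sin(th) * sin(rot)
    y <- -0.2 + 1.2 * cos(th) * sin(rot) + 0.8 * sin(th) * cos(rot)
    f <- fit_ellipse(x, y)
    expect_equal(f$center_i, 0.3, tolerance = 1e-6)
    expect_equal(f$center_q, -0.2, tolerance = 1e-6)
    expect_equal(f$semi_axis_major, 1.2, tolerance = 1e-6)
    expect_equal(f$semi_axis_minor, 0.8, tolerance = 1e-6)
    expect_equal(f$rotation, rot, tolerance = 1e-6)
    expect_lt(f$rms_residual, 1e-10)
  })

  expect_error(fit_ellipse(1:3, 2 * (1:3)), "at least 6")
  expect_error(fit_ellipse(1:10, 2 * (1:10) + 1), "degenerate|ellipse")
})

test_that("compensation projects noiseless ellipse points onto the unit circle", {
  dist <- list(dc_offset_i = 0.3, dc_offset_q = -0.2, amplitude_i = 1.1,
               amplitude_q = 0.85, phase_error = 0.25)
  phi <- seq(0, 2 * pi, length.out = 400)
  i <- dist$dc_offset_i + dist$amplitude_i * cos(phi)
  q <- dist$dc_offset_q + dist$amplitude_q * sin(phi + dist$phase_error)
  fit <- fit_ellipse(i, q)
  cc <- compensate(i, q, fit)
  expect_length(cc$i, length(i))
  expect_lt(max(abs(sqrt(cc$i^2 + cc$q^2) - 1)), 1e-8)

  # identity distortion: circle stays a circle
  cc2 <- compensate(cos(phi), sin(phi), fit_ellipse(cos(phi), sin(phi)))
  expect_lt(max(abs(sqrt(cc2$i^2 + cc2$q^2) - 1)), 1e-8)
})

test_that("arctangent demodulation inverts a known phase exactly", {
  t <- (0:9999) / 1000
  phi <- 0.5 * sin(2 * pi * 1 * t)
  ds <- arctan_demodulate(cos(phi), sin(phi), 1000, wavelength = 12.4)
  expect_equal(ds$phase, phi - phi[1], tolerance = 1e-9)
  expect_identical(ds$values[1], 0)
  # closed-form displacement scale: 0.5 rad * lambda/(4 pi)
  expect_equal(max(ds$values), (0.5 - phi[1]) * 12.4 / (4 * pi),
               tolerance = 1e-9)
  expect_error(arctan_demodulate(c(1, 0), c(0, 0), 1000), "zero-magnitude")
})

test_that("full demodulation round trip recovers the simulated displacement", {
  prof <- list(resp_amplitude = 4, resp_rate = 0.25, heart_rate_mean = 72,
               heart_rate_sd = 2, pulse_amplitude = 0.45, pulse_width = 0.12,
               noise_sd = 0)
  dist <- list(dc_offset_i = 0.3, dc_offset_q = -0.2, amplitude_i = 1.1,
               amplitude_q = 0.85, phase_error = 0.25)
  d <- chest_displacement(prof, 10, 2000, seed = 3)

  rec <- modulate_iq(d$total, dist, 12.4, noise_sd = 0, fs = 2000, seed = 4)
  win <- demodulate_recording(rec)
  expect_gt(stats::cor(win$displacement[[1]], d$total), 0.99)

  # fitted center matches generating DC offsets (noiseless)
  expect_equal(win$ellipse[[1]]$center_i, 0.3, tolerance = 1e-4)
  expect_equal(win$ellipse[[1]]$center_q, -0.2, tolerance = 1e-4)

  # 30 dB SNR on unit-amplitude channels
  rec30 <- modulate_iq(d$total, dist, 12.4, noise_sd = sqrt(1e-3) / sqrt(2),
                       fs = 2000, seed = 5)
  win30 <- demodulate_recording(rec30)
  expect_gt(stats::cor(win30$displacement[[1]], d$total), 0.95)
})
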
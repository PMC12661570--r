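test_that("cohort sampling honors exact class counts and seeding", {
  cfg <- cohort_config(n_subjects = 30, sex_proportions = c(14 / 30, 16 / 30),
                       duration_per_subject = 10, seed = 3)
  prof <- sample_cohort(cfg)
  expect_equal(nrow(prof), 30)
  expect_equal(sum(prof$sex_label == 0), 14)
  expect_equal(sum(prof$sex_label == 1), 16)
  expect_identical(prof, sample_cohort(cfg))
  expect_true(all(prof$heart_rate_mean >= 40 & prof$heart_rate_mean <= 180))
  expect_true(all(prof$pulse_amplitude < prof$resp_amplitude))
  expect_true(all(abs(prof$phase_error) < pi / 2))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(duration_per_subject = 5), "duration")
  expect_error(cohort_config(n_subjects = 10,
                             sex_proportions = c(0.01, 0.99)),
               "at least one subject")
})

test_that("null effect size makes the class-conditional draws exchangeable", {
  cfg0 <- cohort_config(n_subjects = 200, effect_size = 0, seed = 9)
  prof <- sample_cohort(cfg0)
  d <- mean(prof$heart_rate_mean[prof$sex_label == 1]) -
    mean(prof$heart_rate_mean[prof$sex_label == 0])
  # difference of class means is a mean-zero draw with sd ~ 6*sqrt(2/100)
  expect_lt(abs(d), 3 * 6 * sqrt(2 / 100))
  cfg2 <- cohort_config(n_subjects = 200, effect_size = 2, seed = 9)
  prof2 <- sample_cohort(cfg2)
  d2 <- mean(prof2$heart_rate_mean[prof2$sex_label == 1]) -
    mean(prof2$heart_rate_mean[prof2$sex_label == 0])
  expect_gt(d2, 6)  # 2 pooled sds = 12 bpm, well clear of sampling noise
})

test_that("chest displacement components behave as specified", {
  base <- list(resp_amplitude = 0, resp_rate = 0.25, heart_rate_mean = 60,
               heart_rate_sd = 0, pulse_amplitude = 0, pulse_width = 0.12,
               noise_sd = 0)
  d0 <- chest_displacement(base, 10, 2000, seed = 1)
  expect_true(all(d0$total == 0))
  expect_true(all(d0$cardiac == 0))

  # rate arithmetic: 60 bpm, zero variability, 10 s -> 10 +/- 1 beats
  p <- utils::modifyList(base, list(pulse_amplitude = 0.5))
  for (s in 1:5) {
    d <- chest_displacement(p, 10, 2000, seed = s)
    expect_true(abs(length(d$beat_times) - 10) <= 1)
  }

  # dominant spectral peak of the cardiac train near heart_rate_mean/60
  p2 <- utils::modifyList(base, list(pulse_amplitude = 0.5,
                                     heart_rate_mean = 72,
                                     heart_rate_sd = 1))
  d2 <- chest_displacement(p2, 30, 500, seed = 2)
  spec <- stats::spec.pgram(d2$cardiac - mean(d2$cardiac), plot = FALSE,
                            taper = 0, detrend = FALSE)
  freq <- spec$freq * 500
  keep <- freq > 0.5 & freq < 3
  peak <- freq[keep][which.max(spec$spec[keep])]
  expect_lt(abs(peak - 72 / 60), 0.1)
})

test_that("quadrature modulation follows the two-way phase model", {
  dist <- list(dc_offset_i = 0.2, dc_offset_q = -0.1, amplitude_i = 1.1,
               amplitude_q = 0.9, phase_error = 0.2)
  # static target: constant channels
  rec <- modulate_iq(rep(0, 100), dist, wavelength = 12.4, noise_sd = 0,
                     fs = 100, seed = 1, phi0 = 0.5)
  expect_equal(rec$i, rep(0.2 + 1.1 * cos(0.5), 100))
  expect_equal(rec$q, rep(-0.1 + 0.9 * sin(0.5 + 0.2), 100))

  # displacement amplitude lambda/4 -> phase swing of exactly +/- pi
  lam <- 12.4
  disp <- (lam / 4) * sin(2 * pi * 1 * (0:999) / 1000)
  rec2 <- modulate_iq(disp, dist, wavelength = lam, noise_sd = 0, fs = 1000,
                      seed = 1, phi0 = 0)
  phase <- 4 * pi * disp / lam
  expect_equal(max(phase), pi, tolerance = 1e-6)

  # noiseless points satisfy the generating conic to machine precision
  x <- rec2$i - dist$dc_offset_i
  y <- rec2$q - dist$dc_offset_q
  # (x/Ai)^2 + ((y/Aq) - (x/Ai) sin(eps))^2 / cos(eps)^2 = 1
  u <- x / dist$amplitude_i
  v <- y / dist$amplitude_q
  res <- u^2 + (v - u * sin(dist$phase_error))^2 / cos(dist$phase_error)^2 - 1
  expect_lt(max(abs(res)), 1e-10)

  expect_error(modulate_iq(numeric(0), dist), "non-empty")
})

test_that("dataset generation writes a consistent, reproducible manifest", {
  cfg <- cohort_config(n_subjects = 4, sex_proportions = c(0.5, 0.5),
                       duration_per_subject = 30, seed = 21)
  out <- withr::local_tempdir()
  man <- generate_dataset(cfg, out)
  expect_equal(nrow(man), 4)
  expect_true(all(file.exists(man$path)))
  rec <- readRDS(man$path[1])
  expect_length(rec$i, 30 * 2000)
  prof <- sample_cohort(cfg)
  expect_equal(man$sex, prof$sex_label)
  expect_equal(man$age_group, prof$age_group_label)

  out2 <- withr::local_tempdir()
  man2 <- generate_dataset(cfg, out2)
  rec2 <- readRDS(man2$path[1])
  expect_identical(rec$i, rec2$i)
  expect_identical(rec$q, rec2$q)
})
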
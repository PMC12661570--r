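#' Cohort configuration for the synthetic radar study
#'
#' Defines the population the simulator draws from: cohort size, the class
#' balance of the two demographic labels (sex, age group), the standardized
#' separation between class-conditional physiological parameters, and the
#' recording geometry. The defaults mirror a small clinical resting-scenario
#' cohort: 30 subjects, a 14/16 sex split, ten-minute-scale recordings cut
#' down to `duration_per_subject`, and I/Q sampling at 2 kHz.
#'
#' @param n_subjects number of subjects.
#' @param sex_proportions length-2 numeric, fraction of subjects with sex
#'   label 0 and 1; converted to exact counts by rounding.
#' @param age_proportions length-2 numeric, fractions for the two age groups.
#' @param effect_size standardized difference (in pooled within-class standard
#'   deviations) between class parameter means; 0 yields identically
#'   distributed classes, so any downstream classifier should sit at chance.
#' @param duration_per_subject recording length in seconds (>= 10).
#' @param fs I/Q sampling rate, Hz.
#' @param wavelength radar carrier wavelength in mm; 12.4 mm corresponds to a
#'   24 GHz continuous-wave radar. Displacement d maps to phase 4*pi*d/lambda.
#' @param noise_sd standard deviation of additive receiver noise (I/Q units)
#'   and of the residual body-motion noise (mm).
#' @param seed integer master seed; everything downstream derives from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 30L,
                          sex_proportions = c(14 / 30, 16 / 30),
                          age_proportions = c(0.5, 0.5),
                          effect_size = 1,
                          duration_per_subject = 60,
                          fs = 2000,
                          wavelength = 12.4,
                          noise_sd = 0.01,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              sex_proportions = sex_proportions,
              age_proportions = age_proportions,
              effect_size = effect_size,
              duration_per_subject = duration_per_subject,
              fs = fs, wavelength = wavelength,
              noise_sd = noise_sd, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  assert_that(cfg$n_subjects >= 2, "n_subjects must be >= 2")
  assert_that(cfg$duration_per_subject >= 10,
              "duration_per_subject must be >= 10 s (one analysis window)")
  assert_that(cfg$wavelength > 0, "wavelength must be positive")
  assert_that(abs(sum(cfg$sex_proportions) - 1) < 1e-8 &&
                abs(sum(cfg$age_proportions) - 1) < 1e-8,
              "class proportions must each sum to 1")
  for (p in list(cfg$sex_proportions, cfg$age_proportions)) {
    counts <- round(p * cfg$n_subjects)
    if (any(counts < 1))
      stop("every class must receive at least one subject", call. = FALSE)
  }
  invisible(cfg)
}

# exact per-class counts from proportions (largest-remainder rounding)
class_counts <- function(prop, n) {
  raw <- prop * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Draw a cohort of subject profiles
#'
#' Samples per-subject physiological parameters from class-conditional
#' distributions. The sex label shifts heart-rate mean, pulse width and pulse
#' amplitude (chest-morphology channel); the age-group label shifts
#' beat-to-beat heart-rate variability (the physiological quantity known to
#' change with age). Class means differ by `effect_size` pooled standard
#' deviations; with `effect_size = 0` the two classes are exchangeable.
#'
#' @param config a [cohort_config()].
#' @return A tibble with one row per subject: labels, physiological
#'   parameters, and the ellipse-distortion parameters of the receiver chain
#'   (DC offsets, I/Q amplitude imbalance, quadrature phase error).
#' @export
sample_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_subjects
  es <- config$effect_size
  sex <- rep(c(0L, 1L), class_counts(config$sex_proportions, n))

  with_seed(config$seed, {
    age <- sample(rep(c(0L, 1L), class_counts(config$age_proportions, n)))

    # class-conditional parameter draws; pooled sds fixed by design
    hr_sd_pool <- 6       # bpm, between-subject spread of mean heart rate
    pw_sd_pool <- 0.015   # s, spread of pulse width
    pa_sd_pool <- 0.05    # mm, spread of pulse amplitude
    hrv_sd_pool <- 0.8    # bpm, spread of beat-to-beat variability

    hr <- stats::rnorm(n, 72 + (sex - 0.5) * es * hr_sd_pool, hr_sd_pool)
    pw <- stats::rnorm(n, 0.12 + (sex - 0.5) * es * pw_sd_pool, pw_sd_pool)
    pa <- stats::rnorm(n, 0.45 + (sex - 0.5) * es * pa_sd_pool, pa_sd_pool)
    hrv <- stats::rnorm(n, 2.5 + (age - 0.5) * es * hrv_sd_pool, hrv_sd_pool)

    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      sex_label = sex,
      age_group_label = age,
      heart_rate_mean = pmin(pmax(hr, 40), 180),
      heart_rate_sd = pmax(hrv, 0.2),
      pulse_amplitude = pmax(pa, 0.05),
      pulse_width = pmin(pmax(pw, 0.05), 0.3),
      resp_rate = stats::runif(n, 0.15, 0.35),
      resp_amplitude = pmax(stats::rnorm(n, 4, 0.5), 1),
      noise_sd = config$noise_sd,
      dc_offset_i = stats::runif(n, -0.5, 0.5),
      dc_offset_q = stats::runif(n, -0.5, 0.5),
      amplitude_i = stats::runif(n, 0.8, 1.2),
      amplitude_q = stats::runif(n, 0.8, 1.2),
      phase_error = stats::runif(n, -0.3, 0.3)
    )
  })
}
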
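#' Synthesize the chest-displacement signal of one subject
#'
#' Builds the thoracic motion a vital-sign radar observes: a slow,
#' high-amplitude respiration oscillation with random phase drift, a fast,
#' low-amplitude cardiac pulse train (one Gaussian bump per beat, inter-beat
#' intervals jittered by the subject's heart-rate variability), and residual
#' white body-motion noise. The cardiac component is also returned on its own
#' as simulation ground truth.
#'
#' @param profile one row of [sample_cohort()] (data frame or list).
#' @param duration seconds to synthesize.
#' @param fs sampling rate, Hz.
#' @param seed integer seed for the stochastic components.
#' @return list with numeric vectors `total` and `cardiac` (both mm) and the
#'   beat-center times `beat_times` (s).
#' @export
chest_displacement <- function(profile, duration, fs = 2000, seed = 1L) {
  assert_that(duration > 0, "duration must be positive")
  assert_that(fs > 0, "fs must be positive")
  profile <- as.list(profile)
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs

  with_seed(seed, {
    # respiration with slow random-walk phase drift
    drift <- cumsum(stats::rnorm(n, 0, 0.05 / sqrt(fs)))
    resp <- profile$resp_amplitude *
      sin(2 * pi * profile$resp_rate * t + stats::runif(1, 0, 2 * pi) + drift)

    # cardiac pulse train
    ibi_mean <- 60 / profile$heart_rate_mean
    ibi_sd <- 60 * profile$heart_rate_sd / profile$heart_rate_mean^2
    n_beats <- ceiling(duration / ibi_mean) + 10L
    ibis <- pmax(stats::rnorm(n_beats, ibi_mean, ibi_sd), 0.25)
    beats <- stats::runif(1, 0, ibi_mean) + cumsum(c(0, ibis))
    beats <- beats[beats < duration]
    sigma <- profile$pulse_width / 2
    cardiac <- numeric(n)
    if (profile$pulse_amplitude > 0) {
      for (b in beats) {
        lo <- max(1L, floor((b - 4 * sigma) * fs) + 1L)
        hi <- min(n, ceiling((b + 4 * sigma) * fs) + 1L)
        idx <- lo:hi
        cardiac[idx] <- cardiac[idx] +
          profile$pulse_amplitude * exp(-((t[idx] - b)^2) / (2 * sigma^2))
      }
    }

    noise <- if (profile$noise_sd > 0) stats::rnorm(n, 0, profile$noise_sd) else numeric(n)
    total <- if (profile$resp_amplitude > 0) resp else numeric(n)
    list(total = total + cardiac + noise, cardiac = cardiac, beat_times = beats)
  })
}

#' Quadrature modulation of a displacement signal
#'
#' Maps chest displacement d(t) to the I/Q channels of a continuous-wave
#' radar receiver: phase Phi(t) = 4*pi*d(t)/lambda + Phi0 (two-way path), with
#' channel distortions of the ellipse type — DC offsets, amplitude imbalance
#' and quadrature phase error — plus additive white receiver noise:
#' I = dc_i + A_i*cos(Phi), Q = dc_q + A_q*sin(Phi + phase_error).
#'
#' @param displacement numeric vector, mm.
#' @param distortion list/row with `dc_offset_i`, `dc_offset_q`,
#'   `amplitude_i`, `amplitude_q`, `phase_error`.
#' @param wavelength carrier wavelength, mm.
#' @param noise_sd receiver noise standard deviation (I/Q units).
#' @param fs sampling rate, Hz.
#' @param seed seed for noise and the random carrier phase offset.
#' @param subject_id identifier carried along the pipeline.
#' @param cardiac optional ground-truth cardiac component to store.
#' @param phi0 optional fixed carrier phase offset (radians); random if NULL.
#' @return A `radar_recording` object.
#' @export
modulate_iq <- function(displacement, distortion, wavelength = 12.4,
                        noise_sd = 0, fs = 2000, seed = 1L,
                        subject_id = "synthetic", cardiac = NULL, phi0 = NULL) {
  assert_that(length(displacement) > 0, "displacement must be non-empty")
  assert_that(wavelength > 0, "wavelength must be positive")
  d <- as.list(distortion)
  assert_that(d$amplitude_i > 0 && d$amplitude_q > 0,
              "channel amplitudes must be positive")
  assert_that(abs(d$phase_error) < pi / 2, "|phase_error| must be < pi/2")
  n <- length(displacement)
  with_seed(seed, {
    if (is.null(phi0)) phi0 <- stats::runif(1, 0, 2 * pi)
    phi <- 4 * pi * displacement / wavelength + phi0
    i <- d$dc_offset_i + d$amplitude_i * cos(phi)
    q <- d$dc_offset_q + d$amplitude_q * sin(phi + d$phase_error)
    if (noise_sd > 0) {
      i <- i + stats::rnorm(n, 0, noise_sd)
      q <- q + stats::rnorm(n, 0, noise_sd)
    }
    new_radar_recording(subject_id, fs, i, q,
                        ground_truth_displacement = displacement,
                        ground_truth_cardiac = cardiac)
  })
}

new_radar_recording <- function(subject_id, fs, i, q,
                                ground_truth_displacement = NULL,
                                ground_truth_cardiac = NULL) {
  assert_that(length(i) == length(q), "I and Q must have equal length")
  structure(list(subject_id = subject_id, fs = fs, i = i, q = q,
                 duration = length(i) / fs,
                 ground_truth_displacement = ground_truth_displacement,
                 ground_truth_cardiac = ground_truth_cardiac),
            class = "radar_recording")
}

#' @export
print.radar_recording <- function(x, ...) {
  cat(sprintf("<radar_recording> subject %s: %.1f s at %g Hz (%d samples)\n",
              x$subject_id, x$duration, x$fs, length(x$i)))
  invisible(x)
}

#' Simulate I/Q recordings for a whole cohort
#'
#' Convenience wrapper: draws a cohort with [sample_cohort()] and synthesizes
#' one recording per subject, fully determined by the configuration seed.
#'
#' @param config a [cohort_config()].
#' @param profiles optional pre-drawn cohort tibble (defaults to
#'   `sample_cohort(config)`).
#' @return The cohort tibble with a `recording` list-column of
#'   `radar_recording` objects.
#' @export
simulate_cohort <- function(config, profiles = NULL) {
  profiles <- profiles %||% sample_cohort(config)
  seeds <- derive_seeds(config$seed + 1L, 2L * nrow(profiles))
  recs <- purrr::map(seq_len(nrow(profiles)), function(k) {
    p <- profiles[k, ]
    disp <- chest_displacement(p, config$duration_per_subject, config$fs,
                               seed = seeds[2 * k - 1])
    modulate_iq(disp$total, p, wavelength = config$wavelength,
                noise_sd = p$noise_sd, fs = config$fs, seed = seeds[2 * k],
                subject_id = p$subject_id, cardiac = disp$cardiac)
  })
  dplyr::mutate(profiles, recording = recs)
}

#' Materialize a synthetic dataset on disk
#'
#' Writes one file per subject (I/Q arrays plus simulation ground truths and
#' labels) and a manifest CSV (`subject_id, sex, age_group, duration_s, path`).
#' Regeneration from the same configuration is bit-identical.
#'
#' @param config a [cohort_config()].
#' @param out_path output directory (created if missing).
#' @return The manifest as a tibble (invisibly also written to
#'   `manifest.csv` in `out_path`).
#' @export
generate_dataset <- function(config, out_path) {
  dir.create(out_path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_path))
    stop("cannot create output directory: ", out_path, call. = FALSE)
  cohort <- simulate_cohort(config)
  paths <- character(nrow(cohort))
  for (k in seq_len(nrow(cohort))) {
    rec <- cohort$recording[[k]]
    paths[k] <- file.path(out_path, paste0(rec$subject_id, ".rds"))
    saveRDS(rec, paths[k])
  }
  manifest <- tibble::tibble(subject_id = cohort$subject_id,
                             sex = cohort$sex_label,
                             age_group = cohort$age_group_label,
                             duration_s = config$duration_per_subject,
                             path = paths)
  utils::write.csv(manifest, file.path(out_path, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
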
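#' Scalogram rendering configuration
#'
#' @param size output image side in pixels (default 200; smaller sizes are
#'   intended for reduced test profiles only).
#' @param band frequency span in Hz covered by the image rows
#'   (log-spaced, default 0.3-20 Hz).
#' @param omega0 Morlet center frequency (rad), default 6.
#' @return list of class `scalogram_config`.
#' @export
scalogram_config <- function(size = 200L, band = c(0.3, 20), omega0 = 6) {
  assert_that(size >= 8, "image size must be at least 8 px")
  assert_that(band[1] > 0 && band[2] > band[1], "invalid frequency band")
  structure(list(size = as.integer(size), band = band, omega0 = omega0),
            class = "scalogram_config")
}

#' Cut a cardiac window into overlapping frames
#'
#' @param values numeric vector (one analysis window of the cardiac signal).
#' @param fs sampling rate, Hz.
#' @param frame_s frame length in seconds (default 4).
#' @param stride_s hop between frame starts in seconds (default 0.5).
#' @return tibble with `frame_index` (0-based), `start_offset` (s) and a
#'   `values` list-column; a full 10 s window yields exactly 13 frames.
#' @export
segment_frames <- function(values, fs, frame_s = 4, stride_s = 0.5) {
  n <- length(values)
  flen <- round(frame_s * fs)
  step <- round(stride_s * fs)
  if (n < flen)
    stop("window shorter than one ", frame_s, " s frame", call. = FALSE)
  n_frames <- (n - flen) %/% step + 1L
  tibble::tibble(
    frame_index = 0:(n_frames - 1),
    start_offset = (0:(n_frames - 1)) * stride_s,
    values = purrr::map(seq_len(n_frames),
                        ~ values[((.x - 1) * step + 1):((.x - 1) * step + flen)])
  )
}

# Analytic Morlet CWT magnitude on log-spaced frequencies, via FFT.
# The frame is zero-padded (no circular wrap), and each row is compensated
# for edge truncation by the fraction of the wavelet envelope mass inside
# the frame; positions holding less than `min_support` of the envelope are
# zeroed (a 4 s frame cannot support the slowest wavelets near its edges).
morlet_cwt_mag <- function(x, fs, freqs, omega0 = 6, min_support = 0.5) {
  n0 <- length(x)
  x <- c(x - mean(x), numeric(n0))
  n <- length(x)
  fx <- stats::fft(x)
  wgrid <- 2 * pi * fs * (0:(n - 1)) / n
  wgrid[wgrid > pi * fs] <- 0  # negative-frequency half: analytic wavelet is 0 there
  out <- matrix(0, length(freqs), n0)
  t0 <- (seq_len(n0) - 1) / fs
  Tlen <- (n0 - 1) / fs
  for (k in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[k])
    psi <- exp(-((s * wgrid - omega0)^2) / 2)
    psi[wgrid == 0] <- 0
    row <- Mod(stats::fft(fx * psi, inverse = TRUE))[seq_len(n0)] / n
    # envelope mass of the wavelet (time sd = scale) inside the frame
    support <- stats::pnorm((Tlen - t0) / s) - stats::pnorm(-t0 / s)
    row <- ifelse(support < min_support, 0, row / support)
    out[k, ] <- row
  }
  out
}

#' Render one frame as a normalized scalogram image
#'
#' Continuous wavelet transform (analytic Morlet) magnitude on `size`
#' log-spaced frequencies across the configured band. Edge truncation is
#' compensated by the in-frame wavelet envelope mass, and positions where
#' the frame holds less than half of that mass are zeroed (a short frame
#' cannot support the slowest wavelets near its edges). The time axis is
#' reduced to `size` columns by bin averaging and the image min-max
#' normalized to [0, 1] (a constant frame maps to an all-zero image).
#' Row 1 is the highest frequency.
#'
#' @param values numeric vector, one 4 s frame.
#' @param fs sampling rate, Hz.
#' @param config a [scalogram_config()].
#' @return list of class `scalogram`: `pixels` (`size` x `size` matrix in
#'   [0,1]), `freq_axis` (Hz, descending), `time_axis` (s).
#' @export
cwt_scalogram <- function(values, fs, config = scalogram_config()) {
  n <- length(values)
  assert_that(n >= config$size, "frame shorter than the scalogram time axis")
  freqs <- exp(seq(log(config$band[2]), log(config$band[1]),
                   length.out = config$size))  # descending
  mag <- morlet_cwt_mag(values, fs, freqs, config$omega0)
  # reduce time axis to `size` columns by averaging bins
  bins <- adapt_bins(n, config$size)
  px <- matrix(0, config$size, config$size)
  for (b in seq_len(config$size)) {
    px[, b] <- rowMeans(mag[, bins$lo[b]:bins$hi[b], drop = FALSE])
  }
  rng <- range(px)
  px <- if (rng[2] - rng[1] < 1e-15) matrix(0, config$size, config$size)
        else (px - rng[1]) / (rng[2] - rng[1])
  structure(list(pixels = px, freq_axis = freqs,
                 time_axis = ((bins$lo + bins$hi) / 2 - 1) / fs),
            class = "scalogram")
}

#' Compute the scalogram set of a cohort
#'
#' Runs demodulation, cardiac isolation, framing and scalogram rendering for
#' every recording of a simulated cohort, producing the tabular dataset the
#' classifier and the GAN consume.
#'
#' @param cohort tibble from [simulate_cohort()] (needs `recording`,
#'   `subject_id`, `sex_label`, `age_group_label`).
#' @param window_s,frame_s,stride_s framing parameters (s).
#' @param working_fs,wavelet,J,band cardiac-isolation parameters.
#' @param config a [scalogram_config()].
#' @param wavelength carrier wavelength, mm.
#' @return tibble with one row per frame: `subject_id`, `sex_label`,
#'   `age_group_label`, `window_index`, `frame_index`, `provenance`
#'   (`"real"`), and the `pixels` list-column of `size` x `size` matrices.
#' @export
compute_scalograms <- function(cohort, window_s = 10, frame_s = 4,
                               stride_s = 0.5, working_fs = 200,
                               wavelet = "sym4", J = 8, band = c(0.8, 3.5),
                               config = scalogram_config(),
                               wavelength = 12.4) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(k) {
    rec <- cohort$recording[[k]]
    win <- demodulate_recording(rec, window_s, wavelength)
    per_win <- purrr::map(seq_len(nrow(win)), function(w) {
      card <- isolate_cardiac(win$displacement[[w]], win$fs[w],
                              working_fs, wavelet, J, band)
      fr <- segment_frames(card$values, card$fs, frame_s, stride_s)
      tibble::tibble(
        window_index = win$window_index[w],
        frame_index = fr$frame_index,
        pixels = purrr::map(fr$values, ~ cwt_scalogram(.x, card$fs, config)$pixels)
      )
    })
    dplyr::bind_rows(per_win) |>
      dplyr::mutate(subject_id = cohort$subject_id[k],
                    sex_label = cohort$sex_label[k],
                    age_group_label = cohort$age_group_label[k],
                    provenance = "real")
  })
  dplyr::bind_rows(rows) |>
    dplyr::select(dplyr::all_of(c("subject_id", "sex_label", "age_group_label",
                                  "window_index", "frame_index", "provenance",
                                  "pixels")))
}

#' Write a scalogram set to disk as 8-bit grayscale PNGs
#'
#' @param scalograms tibble with columns `pixels`, `label`, `provenance`,
#'   `subject_id`, `window_index`, `frame_index`.
#' @param out_dir output directory (created if missing).
#' @return the manifest tibble (also written as `manifest.csv`), columns
#'   `path, label, provenance, subject_id, window_index, frame_index`.
#' @export
write_scalograms <- function(scalograms, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(scalograms)
  paths <- character(n)
  for (k in seq_len(n)) {
    paths[k] <- file.path(out_dir, sprintf("scal_%05d.png", k))
    png::writePNG(scalograms$pixels[[k]], paths[k])
  }
  manifest <- tibble::tibble(
    path = paths,
    label = scalograms$label %||% rep(NA_integer_, n),
    provenance = scalograms$provenance,
    subject_id = scalograms$subject_id,
    window_index = scalograms$window_index,
    frame_index = scalograms$frame_index
  )
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Read a scalogram set written by [write_scalograms()]
#'
#' @param manifest_path path to the manifest CSV.
#' @return tibble mirroring the written set; pixel values are exact up to
#'   8-bit quantization (<= 1/255 per pixel).
#' @export
read_scalograms <- function(manifest_path) {
  manifest <- tibble::as_tibble(utils::read.csv(manifest_path,
                                                stringsAsFactors = FALSE))
  missing <- !file.exists(manifest$path)
  if (any(missing))
    stop("manifest/file mismatch: ", sum(missing), " image(s) missing",
         call. = FALSE)
  dplyr::mutate(manifest,
                pixels = purrr::map(manifest$path, function(p) {
                  px <- png::readPNG(p)
                  if (length(dim(px)) == 3) px <- px[, , 1]
                  px
                }))
}
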
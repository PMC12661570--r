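#' Cut a recording into non-overlapping analysis windows
#'
#' @param recording a `radar_recording`.
#' @param window_s window length in seconds (default 10).
#' @return tibble with one row per window: `subject_id`, `window_index`
#'   (0-based), `start_time`, `fs`, and list-columns `i`, `q` (and ground
#'   truths when the recording carries them). Trailing samples that do not
#'   fill a window are discarded.
#' @export
segment_windows <- function(recording, window_s = 10) {
  assert_that(inherits(recording, "radar_recording"), "expected a radar_recording")
  fs <- recording$fs
  wlen <- round(window_s * fs)
  n <- length(recording$i)
  n_win <- n %/% wlen
  if (n_win < 1)
    stop("recording shorter than one ", window_s, " s window", call. = FALSE)
  idx <- function(k) ((k - 1) * wlen + 1):(k * wlen)
  tibble::tibble(
    subject_id = recording$subject_id,
    window_index = 0:(n_win - 1),
    start_time = (0:(n_win - 1)) * window_s,
    fs = fs,
    i = purrr::map(seq_len(n_win), ~ recording$i[idx(.x)]),
    q = purrr::map(seq_len(n_win), ~ recording$q[idx(.x)]),
    gt_displacement = purrr::map(seq_len(n_win), function(k) {
      if (is.null(recording$ground_truth_displacement)) NULL
      else recording$ground_truth_displacement[idx(k)]
    }),
    gt_cardiac = purrr::map(seq_len(n_win), function(k) {
      if (is.null(recording$ground_truth_cardiac)) NULL
      else recording$ground_truth_cardiac[idx(k)]
    })
  )
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to an ellipse to a point cloud using the
#' numerically stable partitioned eigen formulation of the direct
#' least-squares method, then converts to geometric parameters. This is the
#' standard estimator for quadrature channel imbalance: the I/Q locus of a
#' moving target is a circle distorted into an ellipse by DC offsets,
#' amplitude imbalance and phase error.
#'
#' @param i,q numeric vectors of equal length (>= 6 points).
#' @return list of class `ellipse_fit`: `center_i`, `center_q`,
#'   `semi_axis_major`, `semi_axis_minor`, `rotation` (radians, in
#'   (-pi/2, pi/2]), and `rms_residual` (algebraic residual of the
#'   normalized conic).
#' @export
fit_ellipse <- function(i, q) {
  assert_that(length(i) == length(q), "i and q must have equal length")
  if (length(i) < 6)
    stop("ellipse fit needs at least 6 points (conic has 5 dof)", call. = FALSE)
  # center/scale for conditioning
  mx <- mean(i); my <- mean(q)
  s <- mean(c(stats::sd(i), stats::sd(q)))
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate geometry: points are coincident", call. = FALSE)
  x <- (i - mx) / s; y <- (q - my) / s

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  if (rcond(S3) < 1e-12)
    stop("degenerate geometry: collinear or rank-deficient points", call. = FALSE)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  # premultiply by inv(C1) for constraint 4ac - b^2 = 1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  evec <- Re(eg$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0)
    stop("degenerate geometry: no elliptical solution", call. = FALSE)
  a1 <- evec[, ok[1]]
  a2 <- Tm %*% a1
  A <- a1[1]; B <- a1[2]; C <- a1[3]
  Dc <- a2[1]; E <- a2[2]; Fc <- a2[3]

  # de-normalize conic back to original coordinates
  # x' = (X - mx)/s etc.; substitute and collect terms
  A0 <- A / s^2
  B0 <- B / s^2
  C0 <- C / s^2
  D0 <- Dc / s - 2 * A * mx / s^2 - B * my / s^2
  E0 <- E / s - 2 * C * my / s^2 - B * mx / s^2
  F0 <- Fc + A * mx^2 / s^2 + B * mx * my / s^2 + C * my^2 / s^2 -
    Dc * mx / s - E * my / s
  conic_to_ellipse(A0, B0, C0, D0, E0, F0, i, q)
}

conic_to_ellipse <- function(A, B, C, D, E, F, i, q) {
  disc <- B^2 - 4 * A * C
  if (disc >= 0) stop("fitted conic is not an ellipse", call. = FALSE)
  cx <- (2 * C * D - B * E) / disc
  cy <- (2 * A * E - B * D) / disc
  # axes from the quadratic form eigenvalues
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  root <- sqrt((A - C)^2 + B^2)
  a_len <- -sqrt(num * (A + C + root)) / disc
  b_len <- -sqrt(num * (A + C - root)) / disc
  axes <- sort(c(a_len, b_len), decreasing = TRUE)
  theta <- if (abs(B) < 1e-14 && A <= C) 0
           else if (abs(B) < 1e-14) pi / 2
           else atan2(C - A - root, B)
  # rotation of the MAJOR axis, normalized to (-pi/2, pi/2]
  if (a_len < b_len) theta <- theta + pi / 2
  theta <- ((theta + pi / 2) %% pi) - pi / 2
  if (theta <= -pi / 2) theta <- theta + pi
  # algebraic residual on the normalized conic
  k <- sqrt(A^2 + B^2 + C^2 + D^2 + E^2 + F^2)
  res <- (A * i^2 + B * i * q + C * q^2 + D * i + E * q + F) / k
  structure(list(center_i = cx, center_q = cy,
                 semi_axis_major = axes[1], semi_axis_minor = axes[2],
                 rotation = theta,
                 rms_residual = sqrt(mean(res^2))),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> center (%.4f, %.4f), axes (%.4f, %.4f), rotation %.4f rad, rms %.2e\n",
              x$center_i, x$center_q, x$semi_axis_major, x$semi_axis_minor,
              x$rotation, x$rms_residual))
  invisible(x)
}

#' Project I/Q points onto the unit circle using a fitted ellipse
#'
#' Subtracts the fitted center, rotates the major axis onto the I axis and
#' rescales both axes to one. Because the distortion map (amplitude
#' imbalance + phase error, |phase error| < pi/2) has positive determinant,
#' this whitening recovers the true phase up to an additive constant — no
#' reflection ambiguity arises.
#'
#' @param i,q numeric vectors.
#' @param fit an `ellipse_fit`.
#' @return list with corrected `i`, `q` on the unit circle.
#' @export
compensate <- function(i, q, fit) {
  assert_that(inherits(fit, "ellipse_fit"), "expected an ellipse_fit")
  if (!is.finite(fit$semi_axis_minor) || fit$semi_axis_minor <= 0)
    stop("invalid ellipse fit: non-positive semi-axis", call. = FALSE)
  x <- i - fit$center_i
  y <- q - fit$center_q
  ct <- cos(-fit$rotation); st <- sin(-fit$rotation)
  xr <- ct * x - st * y
  yr <- st * x + ct * y
  list(i = xr / fit$semi_axis_major, q = yr / fit$semi_axis_minor)
}

#' Arctangent demodulation
#'
#' Recovers displacement from imbalance-corrected I/Q: the unwrapped angle
#' atan2(Q, I), anchored to zero at the first sample and scaled by
#' wavelength/(4*pi) (two-way path).
#'
#' @param i_corr,q_corr corrected channels (unit-circle points).
#' @param fs sampling rate, Hz.
#' @param wavelength carrier wavelength, mm.
#' @return list of class `displacement_signal` with `values` (mm), `phase`
#'   (radians, unwrapped, first sample 0) and `fs`.
#' @export
arctan_demodulate <- function(i_corr, q_corr, fs, wavelength = 12.4) {
  assert_that(length(i_corr) == length(q_corr), "channel length mismatch")
  r2 <- i_corr^2 + q_corr^2
  if (any(r2 < 1e-24))
    stop("zero-magnitude I/Q sample: phase undefined", call. = FALSE)
  phase <- unwrap_phase(atan2(q_corr, i_corr))
  phase <- phase - phase[1]
  structure(list(values = wavelength / (4 * pi) * phase,
                 phase = phase, fs = fs),
            class = "displacement_signal")
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  jumps <- -2 * pi * cumsum(round(dp / (2 * pi)))
  c(p[1], p[-1] + jumps)
}

#' Demodulate every window of a recording
#'
#' Pipeline convenience: [segment_windows()] then, per window, ellipse fit,
#' imbalance compensation and arctangent demodulation.
#'
#' @param recording a `radar_recording`.
#' @param window_s window length in seconds.
#' @param wavelength carrier wavelength, mm.
#' @return the window tibble with list-columns `displacement` (mm) and
#'   `ellipse` (the per-window fits).
#' @export
demodulate_recording <- function(recording, window_s = 10, wavelength = 12.4) {
  win <- segment_windows(recording, window_s)
  fits <- purrr::map(seq_len(nrow(win)), function(k) {
    fit_ellipse(win$i[[k]], win$q[[k]])
  })
  disp <- purrr::map(seq_len(nrow(win)), function(k) {
    cc <- compensate(win$i[[k]], win$q[[k]], fits[[k]])
    arctan_demodulate(cc$i, cc$q, win$fs[k], wavelength)$values
  })
  dplyr::mutate(win, ellipse = fits, displacement = disp)
}
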
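# Maximal overlap discrete wavelet transform (MODWT) and its additive
# multiresolution analysis, with periodic (circular) boundary handling.
# Undecimated: every coefficient vector has the length of the input, the
# analysis is shift-equivariant, and coefficient energies sum to the input
# energy. Filters are stored as DWT (unit-norm) filters and rescaled by
# 1/sqrt(2) per level as the MODWT definition requires.

# least-asymmetric (symlet) scaling filters: order 4 (L = 8) and order 8
# (L = 16, sharper octave transitions)
SYM4_DEC_LO <- c(-0.07576571478927333, -0.02963552764599851,
                  0.49761866763201545,  0.80373875180591614,
                  0.29785779560527736, -0.09921954357684722,
                 -0.01260396726203783,  0.03222310060404270)
SYM8_DEC_LO <- c(-0.00338241595100613, -0.00054213233179115,
                  0.03169508781149298,  0.00760748732491761,
                 -0.14329423835080971, -0.06127335906765852,
                  0.48135965125837221,  0.77718575170052351,
                  0.36444189483533140, -0.05194583810770904,
                 -0.02721902991705600,  0.04913717967360751,
                  0.00380875201389062, -0.01495225833704823,
                 -0.00030292051472137,  0.00188995033275946)

wavelet_filters <- function(wavelet = "sym4") {
  g <- switch(wavelet,
              sym4 = SYM4_DEC_LO,
              sym8 = SYM8_DEC_LO,
              haar = c(1, 1) / sqrt(2),
              d4 = c(0.48296291314469025, 0.83651630373746899,
                     0.22414386804185735, -0.12940952255092145),
              stop("unknown wavelet: ", wavelet))
  L <- length(g)
  # quadrature mirror: h[l] = (-1)^l g[L-1-l]
  h <- (-1)^(0:(L - 1)) * rev(g)
  list(g = g, h = h, L = L)
}

circ_filter <- function(x, f, shift_step, conj = FALSE) {
  # y[t] = sum_l f[l] x[(t -/+ shift_step*l) mod N]
  N <- length(x)
  y <- numeric(N)
  t0 <- 0:(N - 1)
  for (l in seq_along(f)) {
    s <- shift_step * (l - 1)
    idx <- if (conj) (t0 + s) %% N else (t0 - s) %% N
    y <- y + f[l] * x[idx + 1]
  }
  y
}

#' Maximal overlap discrete wavelet transform
#'
#' @param x numeric vector.
#' @param wavelet `"sym4"` (default), `"haar"` or `"d4"`.
#' @param J decomposition depth; must satisfy `J <= floor(log2(length(x)))`.
#' @return list with `W` (list of J detail coefficient vectors), `V`
#'   (level-J scaling coefficients), `wavelet`, `J`. All vectors have
#'   `length(x)` elements (no decimation).
#' @export
modwt <- function(x, wavelet = "sym4", J = 4) {
  N <- length(x)
  assert_that(J >= 1 && J <= floor(log2(N)),
              paste0("J must be in [1, ", floor(log2(N)), "] for this input"))
  flt <- wavelet_filters(wavelet)
  gt <- flt$g / sqrt(2)
  ht <- flt$h / sqrt(2)
  W <- vector("list", J)
  V <- x
  for (j in seq_len(J)) {
    step <- 2^(j - 1)
    W[[j]] <- circ_filter(V, ht, step)
    V <- circ_filter(V, gt, step)
  }
  list(W = W, V = V, wavelet = wavelet, J = J)
}

imodwt_step <- function(Wj, Vj, wavelet, j) {
  flt <- wavelet_filters(wavelet)
  gt <- flt$g / sqrt(2)
  ht <- flt$h / sqrt(2)
  step <- 2^(j - 1)
  circ_filter(Wj, ht, step, conj = TRUE) + circ_filter(Vj, gt, step, conj = TRUE)
}

#' MODWT multiresolution analysis
#'
#' Projects the input onto J additive detail components `D1..DJ` plus a
#' smooth `SJ`: `x == SJ + sum(Dj)` to machine precision, and a circular
#' shift of the input circularly shifts every component (the property that
#' makes the undecimated transform suitable for beat-aligned analysis).
#' Detail `Dj` occupies the nominal octave band `[fs/2^(j+1), fs/2^j]`.
#'
#' @inheritParams modwt
#' @param fs sampling rate in Hz (recorded for band bookkeeping).
#' @param boundary `"periodic"` (circular, exactly shift-equivariant),
#'   `"reflection"` (mirror extension, truncated back), or `"bridge"`
#'   (append a cubic Hermite segment joining the window's final value and
#'   slope back to its initial value and slope, making the circularized
#'   signal C1-continuous; this suppresses the broadband leakage that a wrap
#'   or mirror kink injects into aperiodic windows carrying large slow
#'   components).
#' @param bridge_s bridge length in seconds (boundary `"bridge"` only).
#' @return list of class `mra_decomposition`: `details` (list of J vectors),
#'   `smooth`, `fs`, `levels`, `wavelet_name`.
#' @export
modwt_mra <- function(x, wavelet = "sym4", J = 4, fs = 1,
                      boundary = c("periodic", "reflection", "bridge"),
                      bridge_s = 4) {
  boundary <- match.arg(boundary)
  if (boundary == "reflection") {
    ext <- modwt_mra(c(x, rev(x)), wavelet, J, fs, boundary = "periodic")
    keep <- seq_along(x)
    ext$details <- lapply(ext$details, function(d) d[keep])
    ext$smooth <- ext$smooth[keep]
    return(ext)
  }
  if (boundary == "bridge") {
    ext <- modwt_mra(bridge_extend(x, fs, bridge_s), wavelet, J, fs,
                     boundary = "periodic")
    keep <- seq_along(x)
    ext$details <- lapply(ext$details, function(d) d[keep])
    ext$smooth <- ext$smooth[keep]
    return(ext)
  }
  w <- modwt(x, wavelet, J)
  N <- length(x)
  zero <- numeric(N)
  details <- vector("list", J)
  for (j in seq_len(J)) {
    # invert keeping only W_j
    v <- imodwt_step(w$W[[j]], zero, wavelet, j)
    if (j > 1) for (k in (j - 1):1) v <- imodwt_step(zero, v, wavelet, k)
    details[[j]] <- v
  }
  smooth <- w$V
  for (k in J:1) smooth <- imodwt_step(zero, smooth, wavelet, k)
  structure(list(details = details, smooth = smooth, fs = fs,
                 levels = J, wavelet_name = wavelet),
            class = "mra_decomposition")
}

# C1-continuous circularization: cubic Hermite segment from the window's
# final (value, slope) state back to its initial state; endpoint slopes are
# estimated by short local linear fits for noise robustness
bridge_extend <- function(x, fs, bridge_s = 4) {
  n <- length(x)
  B <- max(4L, round(bridge_s * fs))
  m <- min(n, max(3L, round(0.25 * fs)))
  local_slope <- function(idx) {
    tt <- seq_along(idx)
    unname(stats::coef(stats::lm.fit(cbind(1, tt), x[idx]))[2])
  }
  s0 <- local_slope((n - m + 1):n)   # per-sample slope at the end
  s1 <- local_slope(1:m)             # per-sample slope at the start
  u <- (1:B) / (B + 1)
  h00 <- 2 * u^3 - 3 * u^2 + 1
  h10 <- u^3 - 2 * u^2 + u
  h01 <- -2 * u^3 + 3 * u^2
  h11 <- u^3 - u^2
  br <- h00 * x[n] + h10 * (B + 1) * s0 + h01 * x[1] + h11 * (B + 1) * s1
  c(x, br)
}

#' @export
print.mra_decomposition <- function(x, ...) {
  cat(sprintf("<mra_decomposition> %s, J = %d, fs = %g Hz, n = %d\n",
              x$wavelet_name, x$levels, x$fs, length(x$smooth)))
  invisible(x)
}
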
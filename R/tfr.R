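#' Short-time Fourier spectrogram of a wave segment
#'
#' Windowed DFT power spectral density on a time-frequency grid. The default
#' window is a Hann window of length `min(64, segment length / 4)` (rounded up
#' to even, at least 4) with 75% overlap, zero-padded to a 256-point DFT so
#' short wave segments still get a usable frequency axis. The PSD is one-sided
#' and density-scaled (`|X|^2 / (fs * sum(w^2))`, interior bins doubled) so
#' that `sum(psd) * df * dt` approximates the signal energy.
#'
#' @param segment a `wave_segment`, [ecg_record], or plain numeric vector.
#' @param fs sampling rate (taken from the object when available).
#' @param window_length Hann window length in samples; `NULL` for the default.
#' @param overlap fractional window overlap in `[0, 1)` (default 0.75).
#' @param nfft DFT length (default `max(256, window_length)`).
#' @return An object of class `tf_grid`: list with `t` (s, frame centers),
#'   `f` (Hz), `psd` (matrix `|f| x |t|`), `window`, `hop`, `fs`.
#' @export
stft_spectrogram <- function(segment, fs = NULL, window_length = NULL,
                             overlap = 0.75, nfft = NULL) {
  x <- segment_samples(segment)
  fs <- fs %||% segment_fs(segment)
  n <- length(x)
  if (is.null(window_length)) {
    window_length <- min(64L, ceiling(n / 4))
    if (window_length %% 2L == 1L) window_length <- window_length + 1L
    window_length <- max(4L, window_length)
  }
  wl <- as.integer(window_length)
  if (wl < 4L) stop("window length must be at least 4", call. = FALSE)
  if (n < wl) {
    stop("segment shorter than the analysis window (", wl, " samples)",
         call. = FALSE)
  }
  if (is.null(nfft)) nfft <- max(256L, wl)
  hop <- max(1L, round(wl * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, wl - 1) / (wl - 1))  # Hann
  starts <- seq(1L, n - wl + 1L, by = hop)
  nb <- nfft %/% 2L + 1L
  psd <- matrix(0, nrow = nb, ncol = length(starts))
  scale <- 1 / (fs * sum(w^2))
  for (j in seq_along(starts)) {
    frame <- x[starts[j]:(starts[j] + wl - 1L)] * w
    X <- stats::fft(c(frame, numeric(nfft - wl)))[seq_len(nb)]
    p <- Mod(X)^2 * scale
    # one-sided: double everything except DC and Nyquist
    mid <- seq(2L, nb - if (nfft %% 2L == 0L) 1L else 0L)
    p[mid] <- 2 * p[mid]
    psd[, j] <- p
  }
  structure(list(
    t = (starts + (wl - 1) / 2 - 1) / fs,
    f = seq(0L, nfft %/% 2L) * fs / nfft,
    psd = psd,
    window = list(type = "hann", length = wl),
    hop = hop, fs = fs
  ), class = "tf_grid")
}

#' Convert a PSD matrix to clipped decibels
#'
#' `Z = 10 * log10(psd + 1e-12)`, clipped to the fixed display range
#' \[-120, 120\] dB. Monotone non-decreasing in the input and idempotent
#' after clipping.
#'
#' @param psd_matrix non-negative matrix (or vector).
#' @return Matrix of the same shape with values in \[-120, 120\].
#' @examples
#' psd_to_db(c(0, 1, 1e13)) # -120, ~0, 120
#' @export
psd_to_db <- function(psd_matrix) {
  if (any(psd_matrix < 0)) stop("PSD values must be >= 0", call. = FALSE)
  z <- 10 * log10(psd_matrix + 1e-12)
  z[z < -120] <- -120
  z[z > 120] <- 120
  z
}

#' Polar mapping of a time-frequency grid
#'
#' Maps time to angle and frequency to radius: `theta` spans `[-pi, pi]` in
#' exactly `T` uniform steps, `rho = max(f)/3 + f` (the `max(f)/3` offset
#' forms the inner "pupil" of the iris), and `X = rho cos(theta)`,
#' `Y = rho sin(theta)` on the outer-product grid.
#'
#' @param T length of the time vector (>= 2).
#' @param f frequency vector (non-empty, `max(f) > 0`).
#' @return List with `theta` (length `T`), `rho` (length `|f|`), and matrices
#'   `X`, `Y` of shape `|f| x T`.
#' @examples
#' polar_map(3, c(0, 30, 60))$rho # 20 50 80
#' @export
polar_map <- function(T, f) {
  T <- as.integer(T)
  if (T < 2L) stop("time vector must have at least 2 points", call. = FALSE)
  if (length(f) == 0L || max(f) <= 0) {
    stop("'f' must be non-empty with max(f) > 0", call. = FALSE)
  }
  theta <- seq(-pi, pi, length.out = T)
  rho <- max(f) / 3 + f
  list(theta = theta, rho = rho,
       X = outer(rho, cos(theta)),
       Y = outer(rho, sin(theta)))
}

#' Irisgram: a spectrogram in polar coordinates
#'
#' Composes [stft_spectrogram] -> [psd_to_db] -> [polar_map]: the signal's
#' amplitude spectrum in dB becomes the height `Z` over an annular `(X, Y)`
#' grid whose inner radius (the "pupil") equals `max(f)/3`; time runs
#' circumferentially over `[-pi, pi]` and frequency radially.
#'
#' @inheritParams stft_spectrogram
#' @return An object of class `irisgram`: list with `theta`, `rho`, `X`, `Y`,
#'   `Z` (dB, clipped to \[-120, 120\]), plus the underlying `t`, `f`, `fs`.
#' @export
irisgram <- function(segment, fs = NULL, window_length = NULL,
                     overlap = 0.75, nfft = NULL) {
  grid <- stft_spectrogram(segment, fs, window_length, overlap, nfft)
  pm <- polar_map(length(grid$t), grid$f)
  structure(list(theta = pm$theta, rho = pm$rho, X = pm$X, Y = pm$Y,
                 Z = psd_to_db(grid$psd), t = grid$t, f = grid$f,
                 fs = grid$fs),
            class = "irisgram")
}

#' @export
print.irisgram <- function(x, ...) {
  cat(sprintf("<irisgram>  %d frequencies x %d time steps, Z in [%.1f, %.1f] dB\n",
              length(x$f), length(x$theta), min(x$Z), max(x$Z)))
  cat(sprintf("  annulus radius [%.2f, %.2f]\n", min(x$rho), max(x$rho)))
  invisible(x)
}

# Table of per-wave frequency bands (Hz) driving the scalogram scale vectors.
# The T band's nominal 0 Hz lower edge is clamped to 0.5 Hz (scale diverges
# at DC).
wave_band <- function(wave_kind) {
  switch(match.arg(wave_kind, c("P", "QRS", "T")),
         P = c(5, 30), QRS = c(8, 50), T = c(0.5, 10))
}

#' Continuous-wavelet scalogram of a wave segment
#'
#' Magnitude surface of the continuous wavelet transform over (translation,
#' scale). The mother wavelet is the analytic Morlet (center frequency
#' `fc = 0.8125` cycles/sample at scale 1, so a scale `a` responds to
#' `fc * fs / a` Hz), evaluated in the frequency domain with L2 scale
#' normalization. The scale vector holds `n_scales` logarithmically spaced
#' scales covering the wave's characteristic frequency band — P: 5–30 Hz,
#' QRS: 8–50 Hz, T: 0.5–10 Hz — so each wave type is analysed with its own
#' scaling. Scales are clamped to `[1, 2 * length(segment)]` samples (with a
#' warning) when the requested band is infeasible at the segment's sampling
#' rate and length.
#'
#' @param segment a `wave_segment` (its `wave` field selects the band), an
#'   [ecg_record], or numeric vector (then `wave_kind` is required).
#' @param wave_kind `"P"`, `"QRS"` or `"T"`; overrides the segment's field.
#' @param fs sampling rate (taken from the object when available).
#' @param n_scales number of scales (default 64).
#' @return An object of class `scalogram`: list with `scales` (samples,
#'   ascending), `times` (s), `W` (complex coefficient matrix
#'   `|scales| x |times|`), `values` (`Mod(W)`), `pseudo_freq` (Hz) and
#'   `wavelet = "morlet"`.
#' @export
cwt_scalogram <- function(segment, wave_kind = NULL, fs = NULL,
                          n_scales = 64L) {
  x <- segment_samples(segment)
  fs <- fs %||% segment_fs(segment)
  if (is.null(wave_kind)) {
    if (inherits(segment, "wave_segment")) wave_kind <- segment$wave
    else stop("'wave_kind' is required for plain numeric input", call. = FALSE)
  }
  n <- length(x)
  if (n < 8L) stop("segment must have at least 8 samples", call. = FALSE)
  fc <- 0.8125
  band <- wave_band(wave_kind)
  a_lo <- fc * fs / band[2]
  a_hi <- fc * fs / band[1]
  a_min <- max(1, a_lo)
  a_max <- min(2 * n, a_hi)
  if (a_min > a_lo + 1e-9 || a_max < a_hi - 1e-9) {
    warning(sprintf(
      "scale vector clamped to [%.1f, %.1f] samples (band %g-%g Hz infeasible at fs %g, n %d)",
      a_min, a_max, band[1], band[2], fs, n), call. = FALSE)
  }
  if (a_max <= a_min) a_max <- a_min * 1.001
  scales <- exp(seq(log(a_min), log(a_max), length.out = n_scales))

  npad <- 2^ceiling(log2(2 * n))
  xf <- stats::fft(c(x, numeric(npad - n)))
  omega <- 2 * pi * (seq_len(npad) - 1) / npad
  omega[omega > pi] <- omega[omega > pi] - 2 * pi
  w0 <- 2 * pi * fc
  W <- matrix(0 + 0i, nrow = n_scales, ncol = n)
  for (k in seq_len(n_scales)) {
    a <- scales[k]
    psi_hat <- pi^(-1 / 4) * sqrt(a) * exp(-(a * omega - w0)^2 / 2)
    psi_hat[omega <= 0] <- 0
    W[k, ] <- stats::fft(xf * psi_hat, inverse = TRUE)[seq_len(n)] / npad
  }
  structure(list(scales = scales, times = (seq_len(n) - 1) / fs,
                 W = W, values = Mod(W),
                 pseudo_freq = fc * fs / scales,
                 wavelet = "morlet", fs = fs, wave = wave_kind),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf(
    "<scalogram %s>  %d scales (%.1f-%.1f Hz pseudo-frequency) x %d samples\n",
    x$wave, length(x$scales), min(x$pseudo_freq), max(x$pseudo_freq),
    ncol(x$W)))
  invisible(x)
}

# amplitude samples of whatever signal container we were handed
segment_samples <- function(x) {
  if (inherits(x, "wave_segment") || inherits(x, "ecg_record")) x$samples
  else as.numeric(x)
}

segment_fs <- function(x) {
  if (inherits(x, "wave_segment") || inherits(x, "ecg_record")) x$fs
  else stop("sampling rate 'fs' required for plain numeric input",
            call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
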
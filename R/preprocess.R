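#' Zero-phase band-pass filtering
#'
#' Removes baseline drift and high-frequency noise outside the diagnostic
#' 0.5–40 Hz band. The filter is a cascade of a 4th-order Butterworth
#' high-pass (low edge) and a 10th-order Butterworth low-pass (high edge),
#' each applied forward–backward so the net response has zero phase and
#' fiducial timing is preserved. Because forward–backward filtering squares
#' the magnitude response, the design cutoffs are analytically pre-shifted
#' (in the bilinear-prewarped domain) so the *net* response is -3 dB at the
#' nominal band edges. The signal is mirror-padded before filtering to
#' suppress start-up transients of the 0.5 Hz edge.
#'
#' @param record an [ecg_record].
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @return A filtered [ecg_record] of identical length and sampling rate.
#' @examples
#' s <- synthesize_record(72, 10)
#' f <- bandpass_filter(s$record)
#' abs(mean(f$samples)) < 1e-3 * max(abs(f$samples))
#' @export
bandpass_filter <- function(record, low_hz = 0.5, high_hz = 40) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= fs / 2) {
    stop("'high_hz' must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  n_hp <- 4L
  n_lp <- 10L
  # net -3 dB at the nominal edge: shift the single-pass cutoff by
  # (sqrt(2)-1)^(-1/(2n)) in the tan-prewarped (analog prototype) domain
  shift <- function(f_hz, order, outward) {
    c0 <- (sqrt(2) - 1)^(-1 / (2 * order))
    w <- tan(pi * f_hz / fs) * if (outward) c0 else 1 / c0
    fs / pi * atan(w)
  }
  f_lo <- shift(low_hz, n_hp, outward = FALSE)
  f_hi <- min(shift(high_hz, n_lp, outward = TRUE), 0.499 * fs)
  hp <- signal::butter(n_hp, f_lo / (fs / 2), type = "high")
  lp <- signal::butter(n_lp, f_hi / (fs / 2), type = "low")

  x <- record$samples
  n <- length(x)
  pad <- min(n - 1L, ceiling(5 * fs))  # ~5 s mirror pad for the 0.5 Hz edge
  xp <- c(x[seq(pad + 1L, 2L)], x, x[seq(n - 1L, n - pad)])
  yp <- signal::filtfilt(lp, signal::filtfilt(hp, xp))
  out <- record
  out$samples <- yp[seq(pad + 1L, pad + n)]
  out
}

#' Amplitude normalization
#'
#' Divides by the maximum absolute amplitude so the largest deflection has
#' magnitude 1. Max-absolute scaling (rather than min–max to \[0, 1\])
#' preserves the zero baseline that the zero-crossing delineation relies on:
#' zero crossings stay at identical indices and every sample keeps its sign.
#'
#' @param record an [ecg_record] with at least one non-zero sample.
#' @return A normalized [ecg_record].
#' @export
normalize_amplitude <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  peak <- max(abs(record$samples))
  if (peak == 0) stop("cannot normalize an all-zero signal", call. = FALSE)
  out <- record
  out$samples <- record$samples / peak
  out
}

#' Trim a record to half peak-to-peak bounds
#'
#' Crops the record so that it starts half an RR interval before the first
#' R peak and ends half an RR interval after the last — on conforming beats
#' this makes the record start with a P wave and end with a T wave. Half
#' distances use integer floor division; bounds are clamped to the record.
#'
#' @param record an [ecg_record].
#' @param r_peaks integer sample indices of at least two R peaks (ascending).
#' @return The trimmed [ecg_record]; the original index of its first sample is
#'   attached as attribute `"trim_start"` so annotations can be re-based.
#' @export
trim_record <- function(record, r_peaks) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(r_peaks) < 2L) {
    stop("trimming needs at least two R peaks", call. = FALSE)
  }
  r <- sort(as.integer(r_peaks))
  n <- length(record$samples)
  k <- length(r)
  start <- max(1L, r[1] - (r[2] - r[1]) %/% 2L)
  stop_ <- min(n, r[k] + (r[k] - r[k - 1L]) %/% 2L - 1L)
  out <- record
  out$samples <- record$samples[start:stop_]
  attr(out, "trim_start") <- start
  out
}

#' Standard preprocessing pipeline
#'
#' Composes [bandpass_filter] -> [wavelet_denoise] -> [normalize_amplitude]
#' (optional) -> [trim_record] (optional, requires detected R peaks). The
#' sampling rate is never changed and the composition is deterministic.
#'
#' @param record an [ecg_record].
#' @param low_hz,high_hz band edges passed to [bandpass_filter].
#' @param wavelet_name,levels passed to [wavelet_denoise].
#' @param normalize logical; apply [normalize_amplitude].
#' @param trim logical; detect R peaks and apply [trim_record].
#' @return A preprocessed [ecg_record].
#' @export
preprocess_record <- function(record, low_hz = 0.5, high_hz = 40,
                              wavelet_name = "db8", levels = 9L,
                              normalize = TRUE, trim = FALSE) {
  out <- bandpass_filter(record, low_hz, high_hz)
  out <- wavelet_denoise(out, wavelet_name, levels)
  if (normalize) out <- normalize_amplitude(out)
  if (trim) {
    r <- detect_r_peaks(out)
    if (length(r) >= 2L) out <- trim_record(out, r)
  }
  out
}
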
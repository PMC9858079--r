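#' Beat morphology template
#'
#' A heartbeat is modelled as a sum of five Gaussian deflections (P, Q, R, S,
#' T), each described by an amplitude (mV), a center offset from the R peak
#' (seconds; R is at 0) and a Gaussian width sigma (seconds). Each deflection
#' is truncated to the region where its absolute value is at least
#' `onset_frac` of its peak, so every wave has an exact, analytically known
#' onset and offset on a zero baseline.
#'
#' Default amplitudes follow typical adult lead-II values: P 0.25 mV, R 1.6 mV
#' (the largest wave), T 0.3 mV, with small negative Q and S deflections.
#' Timing defaults describe a beat at 72 bpm; [synthesize_record] rescales
#' them with heart rate.
#'
#' @param P,Q,R,S,T numeric length-3 vectors `c(amplitude, center, width)`
#'   (mV, s, s).
#' @param fs default sampling rate in Hz for beats built from this template.
#' @param onset_frac fraction of a deflection's peak amplitude defining its
#'   onset/offset (default 0.01).
#' @return An object of class `beat_template`.
#' @seealso [make_beat], [synthesize_record]
#' @export
beat_template <- function(P = c(0.25, -0.160, 0.020),
                          Q = c(-0.15, -0.028, 0.009),
                          R = c(1.60, 0.000, 0.012),
                          S = c(-0.15, 0.028, 0.009),
                          T = c(0.30, 0.190, 0.035),
                          fs = 360,
                          onset_frac = 0.01) {
  waves <- list(P = P, Q = Q, R = R, S = S, T = T)
  for (w in names(waves)) {
    v <- waves[[w]]
    if (length(v) != 3L || !all(is.finite(v))) {
      stop("wave ", w, " must be c(amplitude, center, width)", call. = FALSE)
    }
    if (v[3] <= 0) stop("wave ", w, " width must be > 0", call. = FALSE)
  }
  amp <- vapply(waves, `[`, numeric(1), 1L)
  ctr <- vapply(waves, `[`, numeric(1), 2L)
  if (abs(amp[["R"]]) < abs(amp[["P"]]) || abs(amp[["R"]]) < abs(amp[["T"]])) {
    stop("R amplitude must dominate P and T amplitudes", call. = FALSE)
  }
  if (!(ctr[["P"]] < ctr[["Q"]] && ctr[["Q"]] < ctr[["R"]] &&
        ctr[["R"]] == 0 && ctr[["R"]] < ctr[["S"]] && ctr[["S"]] < ctr[["T"]])) {
    stop("wave centers must be ordered P < Q < R = 0 < S < T", call. = FALSE)
  }
  if (!is.numeric(fs) || fs <= 0) stop("'fs' must be > 0", call. = FALSE)
  if (onset_frac <= 0 || onset_frac >= 1) {
    stop("'onset_frac' must be in (0, 1)", call. = FALSE)
  }
  structure(list(waves = waves, fs = fs, onset_frac = onset_frac),
            class = "beat_template")
}

#' @export
print.beat_template <- function(x, ...) {
  cat("<beat_template>  fs =", x$fs, "Hz, onset fraction =", x$onset_frac, "\n")
  m <- do.call(rbind, x$waves)
  colnames(m) <- c("amplitude_mV", "center_s", "width_s")
  print(round(m, 4))
  invisible(x)
}

# scale a template's timing (centers and widths) by a factor; Bazett-style
# rate adaptation used by synthesize_record
scale_template <- function(template, factor) {
  template$waves <- lapply(template$waves,
                           function(v) c(v[1], v[2] * factor, v[3] * factor))
  template
}

# analytic fiducial times (s, relative to the R center) of a template.
# A Gaussian a*exp(-(t-c)^2/(2*s^2)) falls to frac*|a| at c +/- s*sqrt(-2*log(frac)).
template_fiducial_times <- function(template) {
  k <- sqrt(-2 * log(template$onset_frac))
  w <- template$waves
  ft <- c(
    P_on    = w$P[2] - k * w$P[3],
    P_peak  = w$P[2],
    P_off   = w$P[2] + k * w$P[3],
    QRS_on  = w$Q[2] - k * w$Q[3],
    Q       = w$Q[2],
    R       = w$R[2],
    S       = w$S[2],
    QRS_off = w$S[2] + k * w$S[3],
    T_on    = w$T[2] - k * w$T[3],
    T_peak  = w$T[2],
    T_off   = w$T[2] + k * w$T[3]
  )
  if (any(diff(ft) < 0) || ft[["P_off"]] > ft[["QRS_on"]] ||
      ft[["QRS_off"]] > ft[["T_on"]]) {
    stop("deflections overlap: wave centers are closer than their widths allow",
         call. = FALSE)
  }
  ft
}

# evaluate the template waveform on a vector of times (s relative to R);
# each deflection is truncated to its onset_frac support
eval_beat <- function(template, t) {
  y <- numeric(length(t))
  k <- sqrt(-2 * log(template$onset_frac))
  for (v in template$waves) {
    if (v[1] == 0) next
    g <- v[1] * exp(-(t - v[2])^2 / (2 * v[3]^2))
    g[abs(t - v[2]) > k * v[3]] <- 0
    y <- y + g
  }
  y
}

#' Build one synthetic heartbeat with analytic fiducials
#'
#' Samples the template waveform on a uniform grid spanning exactly
#' `[P_on, T_off]` and returns the waveform together with the eleven ground
#' truth fiducial sample indices (1-based). Because every deflection is
#' truncated at the `onset_frac` threshold, each fiducial coincides (to within
#' one sample) with the index a zero-crossing scan of the sampled waveform
#' finds.
#'
#' @param template a [beat_template].
#' @param fs sampling rate in Hz; defaults to the template's.
#' @return An object of class `ecg_beat`: list with `samples`, `fs`, `times`
#'   (s relative to the R center) and `fiducials` (named integer vector).
#' @examples
#' b <- make_beat(beat_template())
#' b$fiducials
#' max(b$samples) # ~ 1.6 mV, the R peak
#' @export
make_beat <- function(template, fs = template$fs) {
  stopifnot(inherits(template, "beat_template"))
  ft <- template_fiducial_times(template)
  t <- seq(ft[["P_on"]], ft[["T_off"]] + 1 / fs, by = 1 / fs)
  samples <- eval_beat(template, t)
  fid <- vapply(ft, function(tt) {
    which.min(abs(t - tt))
  }, integer(1))
  if (any(diff(fid) < 0)) {
    stop("sampling rate too low to resolve fiducial ordering", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, times = t, fiducials = fid),
            class = "ecg_beat")
}

#' Rule-based rhythm labelling from heart rate
#'
#' Normal sinus rhythm spans 60–100 bpm (inclusive at both ends); below 60 is
#' bradycardia, above 100 tachycardia.
#'
#' @param bpm heart rate(s) in beats per minute; must be > 0. Vectorized.
#' @return Character vector of rhythm classes.
#' @examples
#' label_rhythm(c(55, 60, 100, 101))
#' @export
label_rhythm <- function(bpm) {
  if (!is.numeric(bpm) || any(!is.finite(bpm)) || any(bpm <= 0)) {
    stop("'bpm' must be positive and finite", call. = FALSE)
  }
  out <- rep("normal", length(bpm))
  out[bpm < 60] <- "bradycardia"
  out[bpm > 100] <- "tachycardia"
  out
}

#' Noise model specification
#'
#' Additive noise for synthetic records: a low-frequency baseline-wander
#' sinusoid, a power-line sinusoid (50 or 60 Hz), and white broadband noise.
#'
#' @param baseline_amp,baseline_hz baseline wander amplitude (mV) and
#'   frequency (Hz).
#' @param powerline_amp,powerline_hz power-line amplitude (mV) and frequency.
#' @param broadband_sd standard deviation of white noise (mV).
#' @param seed optional integer seed making the broadband realization
#'   reproducible.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_amp = 0, baseline_hz = 0.3,
                       powerline_amp = 0, powerline_hz = 50,
                       broadband_sd = 0, seed = NULL) {
  if (baseline_amp < 0 || powerline_amp < 0 || broadband_sd < 0) {
    stop("noise amplitudes must be >= 0", call. = FALSE)
  }
  structure(list(baseline_amp = baseline_amp, baseline_hz = baseline_hz,
                 powerline_amp = powerline_amp, powerline_hz = powerline_hz,
                 broadband_sd = broadband_sd, seed = seed),
            class = "noise_spec")
}

#' Add synthetic noise to a record
#'
#' @param record an [ecg_record].
#' @param noise a [noise_spec].
#' @param seed seed for the broadband component; defaults to `noise$seed`.
#' @return A new [ecg_record] of the same length and sampling rate.
#' @export
add_noise <- function(record, noise, seed = noise$seed) {
  stopifnot(inherits(record, "ecg_record"), inherits(noise, "noise_spec"))
  n <- length(record$samples)
  t <- (seq_len(n) - 1) / record$fs
  y <- record$samples +
    noise$baseline_amp * sin(2 * pi * noise$baseline_hz * t) +
    noise$powerline_amp * sin(2 * pi * noise$powerline_hz * t)
  if (noise$broadband_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(n, 0, noise$broadband_sd))
  }
  out <- record
  out$samples <- y
  out
}

#' Synthesize a single-lead ECG record with ground-truth fiducials
#'
#' Places beats at a fixed RR interval of `60/bpm` seconds (optionally with
#' seeded Gaussian jitter). Wave timing adapts to heart rate: template centers
#' and widths are scaled by `sqrt(RR / RR_ref)` with `RR_ref = 60/72` s, the
#' usual square-root shortening of intervals (notably QT) at faster rates.
#' This keeps beats non-overlapping at tachycardic rates and gives each
#' rhythm class a distinct wave morphology.
#'
#' @param bpm mean heart rate in beats per minute (> 0).
#' @param duration_s record duration in seconds (> 0).
#' @param template a [beat_template].
#' @param noise a [noise_spec]; the default adds no noise.
#' @param seed integer seed driving RR jitter and the noise realization.
#' @param rr_jitter_sd standard deviation (s) of Gaussian RR jitter; 0 by
#'   default (strictly periodic beats).
#' @param rate_adapt logical; apply the square-root timing adaptation
#'   (default `TRUE`).
#' @param id record identifier.
#' @return A list of class `synth_ecg` with elements:
#'   \describe{
#'     \item{record}{the [ecg_record] (rhythm label set from `bpm`)}
#'     \item{truth}{data frame of ground-truth fiducials, one row per beat,
#'       columns `beat` plus the eleven fiducial sample indices}
#'     \item{bpm, rhythm}{record-level rate and class}
#'   }
#' @examples
#' s <- synthesize_record(bpm = 72, duration_s = 10)
#' nrow(s$truth) # 12 beats
#' @export
synthesize_record <- function(bpm, duration_s,
                              template = beat_template(),
                              noise = noise_spec(),
                              seed = NULL,
                              rr_jitter_sd = 0,
                              rate_adapt = TRUE,
                              id = sprintf("synth_%g bpm", bpm)) {
  if (!is.numeric(bpm) || bpm <= 0) stop("'bpm' must be > 0", call. = FALSE)
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("'duration_s' must be > 0", call. = FALSE)
  }
  rr <- 60 / bpm
  if (rate_adapt) {
    template <- scale_template(template, sqrt(rr / (60 / 72)))
  }
  ft <- template_fiducial_times(template)
  left <- -ft[["P_on"]]   # extent before R (s); P_on is negative
  right <- ft[["T_off"]]  # extent after R (s)
  fs <- template$fs
  if (left + right > 0.98 * rr) {
    stop(sprintf(paste0("beats overlap at %g bpm: beat extent %.3f s ",
                        "exceeds the RR interval %.3f s"), bpm,
                 left + right, rr), call. = FALSE)
  }
  # center the beat in its RR slot when it fits, otherwise pack tightly
  r0 <- if (max(left, right) <= rr / 2) rr / 2 else left * 1.01
  r_times <- seq(r0, duration_s, by = rr)
  r_times <- r_times[r_times + right <= duration_s]
  if (length(r_times) == 0L) {
    stop("duration too short for a single complete beat", call. = FALSE)
  }
  if (rr_jitter_sd > 0) {
    jit <- with_seed(seed, stats::rnorm(length(r_times), 0, rr_jitter_sd))
    r_times <- r_times + jit
    # keep beats ordered, inside the record, and non-overlapping
    r_times <- pmin(pmax(r_times, left), duration_s - right)
    gap <- left + right
    for (i in seq_along(r_times)[-1]) {
      if (r_times[i] - r_times[i - 1] < gap) r_times[i] <- r_times[i - 1] + gap
    }
    r_times <- r_times[r_times + right <= duration_s]
  }

  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  samples <- numeric(n)
  fids <- matrix(NA_integer_, nrow = length(r_times),
                 ncol = length(fiducial_names()),
                 dimnames = list(NULL, fiducial_names()))
  for (i in seq_along(r_times)) {
    rt <- r_times[i]
    i0 <- max(1L, floor((rt + ft[["P_on"]]) * fs) + 1L)
    i1 <- min(n, ceiling((rt + ft[["T_off"]]) * fs) + 1L)
    idx <- i0:i1
    samples[idx] <- samples[idx] + eval_beat(template, t[idx] - rt)
    fids[i, ] <- as.integer(round((rt + ft) * fs) + 1L)
  }
  truth <- data.frame(beat = seq_len(nrow(fids)), fids)
  rhythm <- label_rhythm(bpm)
  rec <- ecg_record(samples, fs = fs, id = id, rhythm = rhythm)
  if (noise$baseline_amp > 0 || noise$powerline_amp > 0 ||
      noise$broadband_sd > 0) {
    rec <- add_noise(rec, noise,
                     seed = if (is.null(noise$seed)) seed else noise$seed)
  }
  structure(list(record = rec, truth = truth, bpm = bpm, rhythm = rhythm),
            class = "synth_ecg")
}

#' @export
print.synth_ecg <- function(x, ...) {
  cat(sprintf("<synth_ecg>  %d beats @ %g bpm (%s)\n",
              nrow(x$truth), x$bpm, x$rhythm))
  print(x$record)
  invisible(x)
}
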
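#' Detect R peaks (Pan-Tompkins style)
#'
#' Classic QRS detection chain: 5–15 Hz zero-phase band-pass, five-point
#' derivative, squaring, 150 ms moving-window integration, then adaptive
#' dual-threshold peak picking with a 200 ms refractory period and an RR
#' search-back at half threshold for missed beats. Each accepted detection is
#' refined to the maximum of the input signal within +/-100 ms, so reported
#' indices sit on the R wave itself.
#'
#' The chain is invariant to positive amplitude scaling (thresholds adapt to
#' the signal) and translation-equivariant.
#'
#' @param record a preprocessed (zero-baseline) [ecg_record].
#' @return Integer vector of R-peak sample indices, strictly increasing;
#'   empty when the signal carries no QRS energy.
#' @examples
#' s <- synthesize_record(72, 10)
#' r <- detect_r_peaks(s$record)
#' length(r)
#' @export
detect_r_peaks <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  if (all(x == 0) || n < fs) return(integer(0))

  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  pad <- min(n - 1L, ceiling(fs))
  xp <- c(x[seq(pad + 1L, 2L)], x, x[seq(n - 1L, n - pad)])
  xb <- signal::filtfilt(bp, xp)[seq(pad + 1L, pad + n)]

  # five-point central derivative (zero phase), then square
  d <- c(0, 0, (2 * (xb[-(1:3)])[seq_len(n - 4)] + xb[4:n][seq_len(n - 4)] -
                2 * xb[2:(n - 3)] - xb[1:(n - 4)]) / 8, 0, 0)
  sq <- d^2
  # centered moving-window integration over 150 ms
  w <- max(3L, round(0.15 * fs))
  if (w %% 2L == 0L) w <- w + 1L
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0]
  if (length(cand) == 0L) return(integer(0))

  refr <- round(0.2 * fs)
  init <- mwi[seq_len(min(n, 2L * fs))]
  spki <- max(init)
  npki <- mean(init) / 2
  thr1 <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  rr_hist <- numeric(0)
  last <- -Inf
  for (i in cand) {
    if (i - last < refr) next
    if (mwi[i] >= thr1) {
      peaks <- c(peaks, i)
      if (is.finite(last)) rr_hist <- utils::tail(c(rr_hist, i - last), 8L)
      last <- i
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      # search-back: accept at half threshold if a beat seems missed
      rr_avg <- if (length(rr_hist)) mean(rr_hist) else NA_real_
      if (!is.na(rr_avg) && is.finite(last) && (i - last) > 1.66 * rr_avg &&
          mwi[i] >= 0.5 * thr1) {
        peaks <- c(peaks, i)
        rr_hist <- utils::tail(c(rr_hist, i - last), 8L)
        last <- i
        spki <- 0.25 * mwi[i] + 0.75 * spki
      } else {
        npki <- 0.125 * mwi[i] + 0.875 * npki
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (length(peaks) == 0L) return(integer(0))

  # refine to the signal maximum within +/-100 ms of each integrated peak
  half <- as.integer(round(0.1 * fs))
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period after refinement
  keep <- c(TRUE, diff(refined) >= refr)
  while (!all(keep)) {
    refined <- refined[keep]
    keep <- c(TRUE, diff(refined) >= refr)
  }
  refined
}

#' Locate P and T peaks around each R peak
#'
#' For each beat, the P peak is the signal maximum in a window left of R and
#' the T peak the maximum in a window right of R. Window spans are fractions
#' of the local RR interval: P in `[R - p_frac * RR_prev, R - p_gap_s)` and T
#' in `(R + t_gap_s, R + t_frac * RR_next]`, clamped to the record. Beats
#' whose windows fall outside the record (or collapse) are dropped with a
#' warning.
#'
#' @param record an [ecg_record].
#' @param r_peaks integer R-peak indices from [detect_r_peaks].
#' @param p_frac,t_frac RR fractions bounding the searches (defaults 0.35 and
#'   0.6).
#' @param p_gap_s,t_gap_s guard gaps (s) excluding the QRS complex itself
#'   (defaults 60 ms and 80 ms).
#' @param default_rr_s RR fallback (s) when only one beat is present.
#' @return Data frame with columns `beat`, `R`, `P_peak`, `T_peak`.
#' @export
locate_p_t_peaks <- function(record, r_peaks,
                             p_frac = 0.35, t_frac = 0.6,
                             p_gap_s = 0.060, t_gap_s = 0.080,
                             default_rr_s = 60 / 72) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(r_peaks) < 1L) stop("need at least one R peak", call. = FALSE)
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  r <- sort(as.integer(r_peaks))
  k <- length(r)
  rr <- diff(r)
  rr_prev <- if (k > 1L) c(rr[1], rr) else rep(round(default_rr_s * fs), 1L)
  rr_next <- if (k > 1L) c(rr, rr[k - 1L]) else rep(round(default_rr_s * fs), 1L)

  rows <- lapply(seq_len(k), function(i) {
    p_lo <- max(1L, r[i] - round(p_frac * rr_prev[i]))
    p_hi <- r[i] - round(p_gap_s * fs) - 1L
    t_lo <- r[i] + round(t_gap_s * fs) + 1L
    t_hi <- min(n, r[i] + round(t_frac * rr_next[i]))
    if (p_hi <= p_lo || t_lo >= t_hi) return(NULL)
    p_peak <- p_lo + which.max(x[p_lo:p_hi]) - 1L
    t_peak <- t_lo + which.max(x[t_lo:t_hi]) - 1L
    data.frame(beat = i, R = r[i], P_peak = p_peak, T_peak = t_peak)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    warning(dropped, " beat(s) dropped: P/T search window outside the record",
            call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(beat = integer(0), R = integer(0),
                      P_peak = integer(0), T_peak = integer(0))
  }
  out
}

#' Zero-crossing wave bounds around a peak
#'
#' Scans backward (onset) and forward (offset) from a wave peak until the
#' signal changes sign relative to the peak or hits an exact zero. The index
#' reported is the sample on the far side of the crossing from the peak. When
#' no crossing exists before the record boundary, the boundary index is
#' returned and flagged.
#'
#' @param record an [ecg_record] (or plain numeric vector).
#' @param peak_index sample index of the wave peak; the signal must be
#'   non-zero there.
#' @return Integer vector `c(onset, offset)` with attribute `"clamped"`, a
#'   logical pair flagging boundary fallbacks.
#' @examples
#' x <- c(0, 0.2, 0.9, 0.2, 0, -0.1)
#' find_wave_bounds(x, 3) # onset 1, offset 5
#' @export
find_wave_bounds <- function(record, peak_index) {
  x <- if (inherits(record, "ecg_record")) record$samples else as.numeric(record)
  n <- length(x)
  i <- as.integer(peak_index)
  if (i < 1L || i > n) stop("peak index out of bounds", call. = FALSE)
  s <- sign(x[i])
  if (s == 0) stop("signal must be non-zero at the peak", call. = FALSE)
  clamped <- c(onset = FALSE, offset = FALSE)
  onset <- NA_integer_
  if (i > 1L) {
    for (j in (i - 1L):1L) {
      if (sign(x[j]) != s) { onset <- j; break }
    }
  }
  if (is.na(onset)) { onset <- 1L; clamped["onset"] <- TRUE }
  offset <- NA_integer_
  if (i < n) {
    for (j in (i + 1L):n) {
      if (sign(x[j]) != s) { offset <- j; break }
    }
  }
  if (is.na(offset)) { offset <- n; clamped["offset"] <- TRUE }
  structure(c(onset = onset, offset = offset), clamped = clamped)
}

#' QRS onset and offset by windowed zero-crossing search
#'
#' QRS onset is the last zero crossing in the window from the P-wave offset
#' to the Q trough; QRS offset is the first zero crossing in the window from
#' the S trough to the T-wave onset. The sample on the QRS side of the
#' crossing pair is reported. If a window contains no crossing the window
#' boundary adjacent to Q (resp. S) is returned and flagged.
#'
#' @param record an [ecg_record] (or numeric vector).
#' @param P_off,Q,S,T_on fiducial sample indices with `P_off < Q < S < T_on`.
#' @return Integer vector `c(QRS_on, QRS_off)` with attribute `"fallback"`.
#' @export
find_qrs_bounds <- function(record, P_off, Q, S, T_on) {
  x <- if (inherits(record, "ecg_record")) record$samples else as.numeric(record)
  if (!(P_off < Q && Q < S && S < T_on)) {
    stop("need P_off < Q < S < T_on", call. = FALSE)
  }
  fallback <- c(onset = FALSE, offset = FALSE)
  # crossings as pairs (j, j+1) with differing sign (exact zeros count)
  crossings <- function(lo, hi) {
    if (hi - lo < 1L) return(integer(0))
    j <- seq.int(lo, hi - 1L)
    j[sign(x[j]) != sign(x[j + 1L])]
  }
  cr_on <- crossings(as.integer(P_off), as.integer(Q) - 1L)
  if (length(cr_on)) {
    qrs_on <- max(cr_on) + 1L  # QRS-side sample of the last crossing
  } else {
    qrs_on <- as.integer(Q) - 1L
    fallback["onset"] <- TRUE
  }
  cr_off <- crossings(as.integer(S) + 1L, as.integer(T_on))
  if (length(cr_off)) {
    qrs_off <- min(cr_off)     # QRS-side sample of the first crossing
  } else {
    qrs_off <- as.integer(S) + 1L
    fallback["offset"] <- TRUE
  }
  structure(c(QRS_on = qrs_on, QRS_off = qrs_off), fallback = fallback)
}

#' Delineate all beats of a record
#'
#' Full delineation: R peaks via [detect_r_peaks], P/T peaks via
#' [locate_p_t_peaks], P and T bounds via [find_wave_bounds], Q and S as the
#' signal minima within 80 ms before/after R, and QRS bounds via
#' [find_qrs_bounds]. Beats violating the strict fiducial ordering
#' `P_on < P_peak < P_off <= QRS_on < Q < R < S < QRS_off <= T_on < T_peak <
#' T_off` are dropped with a warning.
#'
#' @param record a preprocessed [ecg_record].
#' @param r_peaks optional precomputed R-peak indices.
#' @param qs_window_s half-window (s) for the Q/S trough searches.
#' @param ... window options forwarded to [locate_p_t_peaks].
#' @return A data frame of class `beat_annotations`: columns `record_id`,
#'   `beat` and the eleven fiducial indices; zero rows when nothing survives.
#' @examples
#' s <- synthesize_record(72, 10)
#' ann <- delineate_beats(s$record)
#' nrow(ann)
#' @export
delineate_beats <- function(record, r_peaks = NULL, qs_window_s = 0.080, ...) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  if (is.null(r_peaks)) r_peaks <- detect_r_peaks(record)
  empty <- data.frame(record_id = character(0), beat = integer(0))
  for (f in fiducial_names()) empty[[f]] <- integer(0)
  class(empty) <- c("beat_annotations", "data.frame")
  if (length(r_peaks) == 0L) return(empty)
  pt <- locate_p_t_peaks(record, r_peaks, ...)
  if (nrow(pt) == 0L) return(empty)

  qsw <- round(qs_window_s * fs)
  rows <- lapply(seq_len(nrow(pt)), function(i) {
    r <- pt$R[i]
    if (x[pt$P_peak[i]] == 0 || x[pt$T_peak[i]] == 0) return(NULL)
    pb <- find_wave_bounds(record, pt$P_peak[i])
    tb <- find_wave_bounds(record, pt$T_peak[i])
    q_lo <- max(1L, r - qsw)
    s_hi <- min(n, r + qsw)
    if (q_lo >= r - 1L || s_hi <= r + 1L) return(NULL)
    q <- q_lo + which.min(x[q_lo:(r - 1L)]) - 1L
    s_ <- r + which.min(x[(r + 1L):s_hi])
    if (!(pb[["offset"]] < q && s_ < tb[["onset"]])) return(NULL)
    qb <- find_qrs_bounds(record, pb[["offset"]], q, s_, tb[["onset"]])
    ann <- c(P_on = pb[["onset"]], P_peak = pt$P_peak[i], P_off = pb[["offset"]],
             QRS_on = qb[["QRS_on"]], Q = q, R = r, S = s_,
             QRS_off = qb[["QRS_off"]], T_on = tb[["onset"]],
             T_peak = pt$T_peak[i], T_off = tb[["offset"]])
    ok <- all(diff(ann[c("P_on", "P_peak", "P_off")]) > 0) &&
      ann[["P_off"]] <= ann[["QRS_on"]] &&
      all(diff(ann[c("QRS_on", "Q", "R", "S", "QRS_off")]) > 0) &&
      ann[["QRS_off"]] <= ann[["T_on"]] &&
      all(diff(ann[c("T_on", "T_peak", "T_off")]) > 0)
    if (!ok) return(NULL)
    data.frame(record_id = record$id, beat = pt$beat[i], t(ann))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    warning(dropped, " beat(s) dropped: fiducial ordering violated",
            call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$beat <- seq_len(nrow(out))
  class(out) <- c("beat_annotations", "data.frame")
  out
}

#' Extract per-wave signal segments
#'
#' Cuts one segment per annotated beat: P waves span `[P_on, P_off)`, QRS
#' complexes `[QRS_on, QRS_off)` and T waves `[T_on, T_off)` (right-open
#' integer ranges). Segments shorter than 3 samples are dropped with a
#' warning. Each segment carries the record's rhythm label.
#'
#' @param record the delineated [ecg_record].
#' @param annotations a `beat_annotations` data frame from [delineate_beats].
#' @param wave_kind `"P"`, `"QRS"` or `"T"`.
#' @return A list of `wave_segment` objects (fields `samples`, `fs`, `wave`,
#'   `label`, `record_id`, `beat`).
#' @export
extract_wave_segments <- function(record, annotations, wave_kind) {
  stopifnot(inherits(record, "ecg_record"))
  wave_kind <- match.arg(wave_kind, c("P", "QRS", "T"))
  cols <- switch(wave_kind,
                 P = c("P_on", "P_off"),
                 QRS = c("QRS_on", "QRS_off"),
                 T = c("T_on", "T_off"))
  segs <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[[cols[1]]][i]
    b <- annotations[[cols[2]]][i] - 1L
    if (b - a + 1L < 3L) return(NULL)
    structure(list(samples = record$samples[a:b], fs = record$fs,
                   wave = wave_kind, label = record$rhythm,
                   record_id = record$id, beat = annotations$beat[i],
                   start = a),
              class = "wave_segment")
  })
  dropped <- sum(vapply(segs, is.null, logical(1)))
  if (dropped > 0L) {
    warning(dropped, " segment(s) dropped: shorter than 3 samples",
            call. = FALSE)
  }
  Filter(Negate(is.null), segs)
}

#' @export
print.wave_segment <- function(x, ...) {
  cat(sprintf("<wave_segment %s>  beat %s of '%s', %d samples @ %g Hz (%s)\n",
              x$wave, x$beat, x$record_id, length(x$samples), x$fs,
              if (is.na(x$label)) "unlabeled" else x$label))
  invisible(x)
}
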
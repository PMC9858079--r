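# Periodized discrete wavelet transform with the Daubechies-8 filter bank.
#
# The orthonormal db8 synthesis filters (16 taps). Analysis is the adjoint of
# synthesis, so perfect reconstruction holds exactly for any even length.
db8_rec_lo <- c(
   5.4415842243104008e-02,  3.1287159091429995e-01,  6.7563073629728976e-01,
   5.8535468365420673e-01, -1.5829105256349306e-02, -2.8401554296154691e-01,
   4.7248457391328279e-04,  1.2874742662047847e-01, -1.7369301001807547e-02,
  -4.4088253930794755e-02,  1.3981027917398282e-02,  8.7460940474057766e-03,
  -4.8703529934515741e-03, -3.9174037337694705e-04,  6.7544940645056933e-04,
  -1.1747678412476953e-04
)
db8_rec_hi <- rev(db8_rec_lo) * rep(c(1, -1), length.out = 16L)

#' Multilevel discrete wavelet decomposition (db8, periodized)
#'
#' One-dimensional pyramid decomposition with the orthonormal Daubechies-8
#' filter bank and periodic boundary handling. The input length must be
#' divisible by `2^levels`; [wavelet_denoise] handles padding for arbitrary
#' lengths.
#'
#' @param x numeric vector; `length(x)` divisible by `2^levels`.
#' @param levels number of decomposition levels.
#' @return A list of class `wavedec`: `approximation` (deepest-level
#'   coefficients) and `details` (list, level 1 = finest).
#' @seealso [waverec], [wavelet_denoise]
#' @export
wavedec <- function(x, levels = 9L) {
  n <- length(x)
  if (n %% 2^levels != 0) {
    stop("length(x) must be divisible by 2^levels", call. = FALSE)
  }
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    stepped <- dwt_step(a)
    a <- stepped$a
    details[[lev]] <- stepped$d
  }
  structure(list(approximation = a, details = details, levels = levels),
            class = "wavedec")
}

#' Multilevel inverse discrete wavelet transform (db8, periodized)
#'
#' @param dec a `wavedec` object from [wavedec].
#' @return Numeric vector reconstructing the original signal (exactly, up to
#'   floating-point rounding, when coefficients are untouched).
#' @export
waverec <- function(dec) {
  stopifnot(inherits(dec, "wavedec"))
  a <- dec$approximation
  for (lev in rev(seq_len(dec$levels))) {
    a <- idwt_step(a, dec$details[[lev]])
  }
  a
}

# single analysis step: a_k = <x, g0(. - 2k)>, d_k = <x, g1(. - 2k)> (circular)
dwt_step <- function(x) {
  n <- length(x)
  L <- length(db8_rec_lo)
  # the +1 phase matches the usual periodized filter alignment
  idx <- (outer(seq(1L, n - 1L, by = 2L), 0:(L - 1L), `+`) %% n) + 1L
  xm <- matrix(x[idx], ncol = L)
  list(a = as.vector(xm %*% db8_rec_lo),
       d = as.vector(xm %*% db8_rec_hi))
}

# single synthesis step: x = sum_k a_k g0(. - 2k) + d_k g1(. - 2k) (circular)
idwt_step <- function(a, d) {
  m <- length(a)
  n <- 2L * m
  L <- length(db8_rec_lo)
  x <- numeric(n)
  pos <- (outer(2L * (seq_len(m) - 1L) + 1L, 0:(L - 1L), `+`) %% n) + 1L
  contrib_a <- outer(a, db8_rec_lo)
  contrib_d <- outer(d, db8_rec_hi)
  for (j in seq_len(L)) {
    x[pos[, j]] <- x[pos[, j]] + contrib_a[, j] + contrib_d[, j]
  }
  x
}

#' Wavelet denoising and baseline removal
#'
#' Decomposes the signal into `levels` levels with the db8 wavelet, soft
#' thresholds the finest detail levels with the universal threshold
#' \eqn{\sigma\sqrt{2\log N}} (\eqn{\sigma} estimated from level-1 details by
#' MAD/0.6745), optionally zeroes the deepest approximation (which carries
#' baseline wander), and reconstructs by the inverse transform. Signals whose
#' length is not divisible by `2^levels` are symmetrically padded and cropped
#' back after reconstruction.
#'
#' @param record an [ecg_record].
#' @param wavelet_name only `"db8"` is supported.
#' @param levels decomposition depth (default 9).
#' @param threshold logical; apply soft thresholding of detail levels 1–2
#'   (`TRUE`) or reconstruct untouched coefficients (`FALSE`).
#' @param remove_baseline logical; zero the level-`levels` approximation.
#' @param detail_levels which detail levels to threshold (default `1:2`).
#' @return A denoised [ecg_record] of identical length and sampling rate.
#' @export
wavelet_denoise <- function(record, wavelet_name = "db8", levels = 9L,
                            threshold = TRUE, remove_baseline = TRUE,
                            detail_levels = 1:2) {
  stopifnot(inherits(record, "ecg_record"))
  if (!identical(wavelet_name, "db8")) {
    stop("only the db8 wavelet is implemented", call. = FALSE)
  }
  x <- record$samples
  n <- length(x)
  block <- 2^levels
  n_pad <- ceiling(n / block) * block
  if (n_pad > 4L * n) {
    stop("record too short for ", levels, "-level decomposition", call. = FALSE)
  }
  if (n_pad > n) {
    pad <- n_pad - n
    # symmetric (mirror) extension on the right
    ext <- x[seq(n - 1L, by = -1L, length.out = pad)]
    if (anyNA(ext)) stop("record too short to pad", call. = FALSE)
    x <- c(x, ext)
  }
  dec <- wavedec(x, levels)
  if (threshold) {
    sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
    thr <- sigma * sqrt(2 * log(length(x)))
    soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
    for (lev in detail_levels) dec$details[[lev]] <- soft(dec$details[[lev]])
  }
  if (remove_baseline) {
    dec$approximation[] <- 0
  }
  y <- waverec(dec)[seq_len(n)]
  out <- record
  out$samples <- y
  out
}
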
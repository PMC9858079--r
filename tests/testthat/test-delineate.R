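test_that("R-peak detection recovers every beat of a clean record", {
  s <- synthesize_record(72, 10)
  r <- detect_r_peaks(s$record)
  expect_length(r, 12)
  expect_true(all(abs(r - s$truth$R) <= round(0.025 * 360)))
  expect_true(all(diff(r) > 0))
})

test_that("a flat signal yields no R peaks", {
  expect_length(detect_r_peaks(ecg_record(numeric(2000), 360)), 0)
})

test_that("R-peak detection survives 10 dB broadband noise", {
  s <- synthesize_record(72, 10)
  sd10 <- sqrt(mean(s$record$samples^2) / 10)
  tol <- round(0.05 * 360)
  for (seed in c(11, 12)) {
    noisy <- add_noise(s$record, noise_spec(broadband_sd = sd10, seed = seed))
    r <- detect_r_peaks(noisy)
    recall <- mean(vapply(s$truth$R,
                          function(rt) any(abs(r - rt) <= tol), logical(1)))
    precision <- mean(vapply(r,
                             function(d) any(abs(s$truth$R - d) <= tol),
                             logical(1)))
    expect_gte(recall, 0.95)
    expect_gte(precision, 0.95)
  }
})

test_that("P and T peaks land inside the beat near the truth", {
  s <- synthesize_record(72, 10)
  pt <- locate_p_t_peaks(s$record, s$truth$R)
  expect_equal(nrow(pt), 12)
  expect_true(all(abs(pt$P_peak - s$truth$P_peak) <= round(0.025 * 360)))
  expect_true(all(abs(pt$T_peak - s$truth$T_peak) <= round(0.025 * 360)))
  # asymmetric template: T sits further from R than P does
  expect_true(all(pt$T_peak - pt$R > pt$R - pt$P_peak))
})

test_that("zero-crossing wave bounds match the hand-traced example", {
  x <- c(0, 0.2, 0.9, 0.2, 0, -0.1)
  b <- find_wave_bounds(x, 3)
  expect_equal(unname(b), c(1, 5), ignore_attr = TRUE)
  # symmetry under negation
  bn <- find_wave_bounds(-x, 3)
  expect_equal(unname(bn), unname(b))
  # positive bump on a zero baseline brackets its support
  g <- c(0, 0, 0.1, 0.5, 1, 0.5, 0.1, 0, 0)
  bb <- find_wave_bounds(g, 5)
  expect_equal(unname(bb), c(2, 8), ignore_attr = TRUE)
  # no crossing anywhere: clamped to the record boundary and flagged
  pos <- rep(0.5, 9)
  bc <- find_wave_bounds(pos, 5)
  expect_equal(unname(bc), c(1, 9), ignore_attr = TRUE)
  expect_true(all(attr(bc, "clamped")))
  expect_error(find_wave_bounds(c(0, 1, 0), 1), "non-zero")
})

test_that("zero-crossing scans agree with an exhaustive search", {
  set.seed(21)
  for (rep_i in 1:20) {
    n <- sample(50:2000, 1)
    x <- rnorm(n)
    peak <- sample(seq(2, n - 1), 1)
    if (x[peak] == 0) next
    b <- find_wave_bounds(x, peak)
    s <- sign(x[peak])
    below <- which(sign(x[seq_len(peak - 1)]) != s)
    above <- peak + which(sign(x[seq(peak + 1, n)]) != s)
    expect_equal(unname(b[1]), if (length(below)) max(below) else 1)
    expect_equal(unname(b[2]), if (length(above)) min(above) else n)
  }
})

test_that("QRS bounds follow the last/first-crossing window rules", {
  # one crossing in each window: both rules return it
  x <- c(0.2, 0.1, -0.3, -1, 2, -1, -0.3, 0.1, 0.2)
  qb <- find_qrs_bounds(x, P_off = 1, Q = 4, S = 6, T_on = 9)
  expect_equal(unname(qb), c(3, 7), ignore_attr = TRUE)
  expect_false(any(attr(qb, "fallback")))
  # strictly positive onset window: boundary fallback, flagged
  x2 <- c(0.2, 0.1, 0.3, 1, 2, -1, -0.3, 0.1, 0.2)
  qb2 <- find_qrs_bounds(x2, P_off = 1, Q = 4, S = 6, T_on = 9)
  expect_equal(unname(qb2[1]), 3)
  expect_true(attr(qb2, "fallback")[["onset"]])
  expect_error(find_qrs_bounds(x, 5, 4, 6, 9), "P_off < Q")
})

test_that("full delineation recovers ground truth across heart rates", {
  for (bpm in c(40, 72, 140)) {
    s <- synthesize_record(bpm, 10)
    ann <- suppressWarnings(delineate_beats(s$record))
    expect_gte(nrow(ann), nrow(s$truth) - 2)  # interior beats all annotated
    errs <- fiducial_errors_ms(ann, s$truth)
    expect_gte(mean(errs <= 20), 0.95)
  }
})

test_that("delineation is translation-equivariant and scale-invariant", {
  s <- synthesize_record(72, 8)
  ann <- suppressWarnings(delineate_beats(s$record))
  k <- 25L
  shifted <- ecg_record(c(numeric(k), s$record$samples), fs = s$record$fs,
                        rhythm = s$rhythm)
  ann_s <- suppressWarnings(delineate_beats(shifted))
  common <- min(nrow(ann), nrow(ann_s))
  expect_equal(as.matrix(ann_s[seq_len(common), FID]),
               as.matrix(ann[seq_len(common), FID]) + k,
               ignore_attr = TRUE)
  scaled <- s$record
  scaled$samples <- 3.7 * scaled$samples
  ann_c <- suppressWarnings(delineate_beats(scaled))
  expect_equal(as.matrix(ann_c[FID]), as.matrix(ann[FID]),
               ignore_attr = TRUE)
})

test_that("wave segments slice the annotated spans and carry labels", {
  s <- synthesize_record(72, 10)
  ann <- suppressWarnings(delineate_beats(s$record))
  qrs <- extract_wave_segments(s$record, ann, "QRS")
  expect_length(qrs, nrow(ann))
  rec_max <- max(s$record$samples)
  for (i in seq_along(qrs)) {
    expect_equal(sum(qrs[[i]]$samples == max(qrs[[i]]$samples)), 1)
    expect_equal(max(qrs[[i]]$samples), rec_max, tolerance = 1e-6)
    expect_equal(qrs[[i]]$label, "normal")
  }
  p <- extract_wave_segments(s$record, ann, "P")
  expect_equal(vapply(p, function(sg) length(sg$samples), numeric(1)),
               ann$P_off - ann$P_on)
  # the three per-beat spans never overlap
  expect_true(all(ann$P_off <= ann$QRS_on & ann$QRS_off <= ann$T_on))
})

test_that("an empty record produces an empty annotation set", {
  ann <- delineate_beats(ecg_record(numeric(4000), 360))
  expect_s3_class(ann, "beat_annotations")
  expect_equal(nrow(ann), 0)
})
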
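test_that("a zero-amplitude template yields an all-zero waveform", {
  tpl <- beat_template(P = c(0, -0.160, 0.020), Q = c(0, -0.028, 0.009),
                       R = c(0, 0, 0.012), S = c(0, 0.028, 0.009),
                       T = c(0, 0.190, 0.035))
  b <- make_beat(tpl)
  expect_true(all(b$samples == 0))
})

test_that("the R deflection dominates the beat at its fiducial", {
  b <- make_beat(beat_template())
  expect_equal(max(b$samples), 1.6, tolerance = 0.02)
  expect_equal(which.max(b$samples), unname(b$fiducials[["R"]]))
})

test_that("analytic onsets/offsets match a brute-force threshold scan", {
  tpl <- beat_template()
  b <- make_beat(tpl, fs = 360)
  k <- sqrt(-2 * log(tpl$onset_frac))
  # oracle: scan each sampled (truncated) deflection for support boundaries
  for (w in c("P", "Q", "S", "T")) {
    v <- tpl$waves[[w]]
    g <- v[1] * exp(-(b$times - v[2])^2 / (2 * v[3]^2))
    g[abs(b$times - v[2]) > k * v[3]] <- 0
    nz <- which(g != 0)
    on_name <- switch(w, P = "P_on", Q = "QRS_on", S = NULL, T = "T_on")
    off_name <- switch(w, P = "P_off", Q = NULL, S = "QRS_off", T = "T_off")
    if (!is.null(on_name)) {
      expect_lte(abs(min(nz) - b$fiducials[[on_name]]), 1)
    }
    if (!is.null(off_name)) {
      expect_lte(abs(max(nz) - b$fiducials[[off_name]]), 1)
    }
  }
  expect_true(all(diff(b$fiducials) >= 0))
})

test_that("templates whose deflections overlap are rejected", {
  tpl <- beat_template(P = c(0.25, -0.04, 0.02))  # P runs into the QRS
  expect_error(make_beat(tpl), "overlap")
})

test_that("beat placement matches floor(duration/RR) and labels the rhythm", {
  s <- synthesize_record(72, 10)
  expect_equal(nrow(s$truth), 12)  # floor(10 / 0.8333)
  expect_equal(diff(s$truth$R), rep(round(60 / 72 * 360), 11))
  expect_equal(s$rhythm, "normal")
  expect_equal(synthesize_record(40, 10)$rhythm, "bradycardia")
  expect_equal(synthesize_record(140, 10)$rhythm, "tachycardia")
})

test_that("fiducial ordering and R = argmax hold for every generated record", {
  for (bpm in c(45, 72, 110, 160)) {
    s <- synthesize_record(bpm, 8)
    m <- as.matrix(s$truth[FID])
    # strictly increasing within beat (ties allowed only at the two joints)
    expect_true(all(m[, "P_on"] < m[, "P_peak"]))
    expect_true(all(m[, "P_peak"] < m[, "P_off"]))
    expect_true(all(m[, "P_off"] <= m[, "QRS_on"]))
    expect_true(all(m[, "QRS_on"] < m[, "Q"] & m[, "Q"] < m[, "R"] &
                      m[, "R"] < m[, "S"] & m[, "S"] < m[, "QRS_off"]))
    expect_true(all(m[, "QRS_off"] <= m[, "T_on"]))
    expect_true(all(m[, "T_on"] < m[, "T_peak"] & m[, "T_peak"] < m[, "T_off"]))
    # beats non-overlapping
    expect_true(all(utils::head(m[, "T_off"], -1) < m[-1, "P_on"]))
    # R fiducial is the argmax of its beat window
    x <- s$record$samples
    for (i in seq_len(nrow(m))) {
      win <- m[i, "P_on"]:m[i, "T_off"]
      expect_equal(win[which.max(x[win])], unname(m[i, "R"]))
    }
  }
})

test_that("synthesis is bit-identical under a fixed seed", {
  ns <- noise_spec(baseline_amp = 0.1, powerline_amp = 0.05,
                   broadband_sd = 0.03, seed = 5)
  a <- synthesize_record(80, 6, noise = ns, rr_jitter_sd = 0.01, seed = 5)
  b <- synthesize_record(80, 6, noise = ns, rr_jitter_sd = 0.01, seed = 5)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$truth, b$truth)
})

test_that("beats that cannot fit the RR interval are rejected", {
  expect_error(synthesize_record(300, 10), "overlap")
  expect_error(synthesize_record(140, 10, rate_adapt = FALSE), "overlap")
})

test_that("rhythm labelling is a step function with breakpoints at 60 and 100", {
  expect_equal(label_rhythm(55), "bradycardia")
  expect_equal(label_rhythm(100), "normal")
  expect_equal(label_rhythm(101), "tachycardia")
  lab <- label_rhythm(seq(1, 220, by = 0.5))
  expect_equal(sort(unique(lab)), sort(rhythm_classes()))
  # monotone: transitions occur exactly once, at 60 and at 100
  codes <- c(bradycardia = 1, normal = 2, tachycardia = 3)[lab]
  expect_true(all(diff(codes) >= 0))
  expect_equal(sum(diff(codes) == 1), 2)
  expect_error(label_rhythm(0), "positive")
})

test_that("additive noise is constructive, seeded and removable", {
  s <- synthesize_record(72, 5)
  same <- add_noise(s$record, noise_spec())
  expect_identical(same$samples, s$record$samples)

  a <- 0.2
  ns <- noise_spec(powerline_amp = a, powerline_hz = 50)
  noisy <- add_noise(s$record, ns)
  delta <- noisy$samples - s$record$samples
  t <- (seq_along(delta) - 1) / s$record$fs
  expect_equal(delta, a * sin(2 * pi * 50 * t), tolerance = 1e-12)

  nb <- noise_spec(broadband_sd = 0.05, seed = 3)
  expect_identical(add_noise(s$record, nb)$samples,
                   add_noise(s$record, nb)$samples)
  expect_equal(length(noisy$samples), length(s$record$samples))
  expect_equal(noisy$fs, s$record$fs)
})

test_that("records round-trip through CSV with metadata intact", {
  s <- synthesize_record(72, 3)
  p <- withr::local_tempfile(fileext = ".csv")
  write_ecg_csv(s$record, p)
  back <- read_ecg_csv(p)
  expect_equal(back$samples, s$record$samples)
  expect_equal(back$fs, s$record$fs)
  expect_equal(back$rhythm, "normal")
  pa <- withr::local_tempfile(fileext = ".csv")
  write_annotations_csv(cbind(record_id = s$record$id, s$truth), pa)
  tr <- read_annotations_csv(pa)
  expect_equal(as.matrix(tr[FID]), as.matrix(s$truth[FID]),
               ignore_attr = TRUE)
})
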
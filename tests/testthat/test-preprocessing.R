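test_that("remove_dc centers the signal and rejects empty input", {
  expect_equal(remove_dc(c(5, 5, 5, 5)), c(0, 0, 0, 0))
  z <- c(-1, 0, 1)
  expect_equal(remove_dc(z), z)
  expect_equal(remove_dc(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(remove_dc(numeric(0)), "empty")
  set.seed(1)
  x <- rnorm(100, mean = 3)
  expect_equal(mean(remove_dc(x)), 0, tolerance = 1e-12)
  expect_length(remove_dc(x), 100)
})

test_that("calibrate applies the affine map and validates gain", {
  x <- c(2, 4)
  expect_equal(calibrate(x), x)
  expect_equal(calibrate(x, gain = 0.5, offset = 2), c(0, 1))
  expect_error(calibrate(x, gain = 0), "non-zero")
})

test_that("rest-derived calibration normalizes the rest segment to unit RMS", {
  set.seed(2)
  rest <- rnorm(2000, mean = 0.3, sd = 0.05)
  cal <- rest_calibration(rest, normalize = TRUE)
  calibrated <- calibrate(rest, cal$gain, cal$offset)
  expect_equal(rms(calibrated), 1, tolerance = 1e-12)
  cal0 <- rest_calibration(rest)
  expect_equal(cal0$gain, 1)
  expect_equal(cal0$offset, mean(rest))
})

test_that("band-pass keeps the EMG band and rejects DC and drift", {
  # pass-band: 100 Hz within 1 dB
  a100 <- steady_amplitude(100, function(x) bandpass(x, 1000))
  expect_gte(a100, 0.89)
  expect_lte(a100, 1.0 + 1e-6)
  # below the high-pass edge: 5 Hz strongly attenuated
  expect_lte(steady_amplitude(5, function(x) bandpass(x, 1000)), 0.1)
  # pure DC: essentially nothing survives
  dc <- rep(1, 4001)
  expect_lte(max(abs(bandpass(dc, 1000)[1000:3000])), 0.01)
  expect_error(bandpass(c(1, 2, 3), 1000, low_hz = 20, high_hz = 600),
               "cutoffs")
  expect_error(bandpass(c(1, 2, 3), 1000, low_hz = 300, high_hz = 100),
               "cutoffs")
})

test_that("notch removes 60 Hz but not the neighbouring EMG band", {
  expect_lte(steady_amplitude(60, function(x) notch(x, 1000)), 0.1)
  expect_gte(steady_amplitude(100, function(x) notch(x, 1000)), 0.9)
  expect_equal(notch(rep(0, 500), 1000), rep(0, 500))
  expect_error(notch(c(1, 2), 1000, f0_hz = 600), "between")
})

test_that("rms matches its closed forms and is sign/permutation invariant", {
  expect_equal(rms(rep(3, 10)), 3)
  t <- seq(0, 1, length.out = 1001)[-1001]  # exactly one period
  expect_equal(rms(sin(2 * pi * t)), 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_error(rms(numeric(0)), "empty")
  set.seed(3)
  x <- rnorm(50)
  expect_equal(rms(-x), rms(x))
  expect_equal(rms(sample(x)), rms(x))
  expect_equal(rms(2.5 * x), 2.5 * rms(x))
})

test_that("extract_windows applies the cue timing, clips, and skips", {
  rec <- recording(matrix(0, 20000, 2), sample_rate = 1000)
  w <- extract_windows(rec, data.frame(onset_s = 10,
                                       movement_label = "Wrist Flexion"))
  expect_equal(w$start, 10.4)
  expect_equal(w$end, 17.5)
  expect_equal(w$label, "Wrist Flexion")
  # empty schedule
  empty <- extract_windows(rec, data.frame(onset_s = numeric(0),
                                           movement_label = character(0)))
  expect_equal(nrow(empty), 0)
  # cue 2 s before the end: clipped with a warning
  expect_warning(
    wc <- extract_windows(rec, data.frame(onset_s = 18,
                                          movement_label = "Wrist Flexion")),
    "clipped")
  expect_equal(wc$end, 20)
  # cue beyond the recording: skipped with a warning
  expect_warning(
    ws <- extract_windows(rec, data.frame(onset_s = 25,
                                          movement_label = "Wrist Flexion")),
    "skipped")
  expect_equal(nrow(ws), 0)
})

test_that("featurize output is zero for zero input and deterministic", {
  rec <- recording(matrix(0, 12000, 3), sample_rate = 1000)
  cues <- data.frame(onset_s = 1, movement_label = "Hand Contraction")
  f <- featurize(rec, cues)
  expect_equal(nrow(f), 1)
  expect_equal(unname(unlist(f[1, -1])), rep(0, 3))
  expect_equal(f$label, "Hand Contraction")
})

test_that("featurize of a windowed sine recovers the pass-band RMS", {
  sr <- 1000
  t <- seq(0, 12, by = 1 / sr)[-1]
  x <- numeric(length(t))
  active <- t > 1.4 & t < 8.5
  x[active] <- sin(2 * pi * 100 * t[active])
  rec <- recording(matrix(x, ncol = 1), sr)
  cues <- data.frame(onset_s = 1, movement_label = "Wrist Flexion")
  f <- featurize(rec, cues)
  # the window covers exactly the active sine: RMS ~ passband gain / sqrt(2)
  tt <- seq(0, 4, by = 1 / sr)
  ref <- notch(bandpass(sin(2 * pi * 100 * tt), sr), sr)
  gain <- rms(ref[1000:3000]) * sqrt(2)   # RMS-based pass-band gain at 100 Hz
  expect_equal(f$C0, gain / sqrt(2), tolerance = 0.05)
})

test_that("featurize is linear: scaling the recording scales every RMS", {
  set.seed(4)
  sr <- 1000
  x <- matrix(rnorm(10000 * 2), ncol = 2)
  cues <- data.frame(onset_s = 0.5, movement_label = "Wrist Flexion")
  f1 <- featurize(recording(x, sr), cues)
  f3 <- featurize(recording(3 * x, sr), cues)
  expect_equal(as.numeric(f3[, -1]), 3 * as.numeric(f1[, -1]),
               tolerance = 1e-9)
})

test_that("channel subset selection restricts the feature vector", {
  set.seed(5)
  rec <- recording(matrix(rnorm(8000 * 4), ncol = 4), 1000)
  cues <- data.frame(onset_s = 0.2, movement_label = "Wrist Flexion")
  f <- featurize(rec, cues, preproc_config(channels = c("C2", "C0")))
  expect_equal(setdiff(names(f), "label"), c("C2", "C0"))
  expect_error(select_channels(rec, "C9"), "unknown channel")
})

test_that("recording CSV round trip preserves samples and metadata", {
  set.seed(6)
  rec <- recording(matrix(rnorm(200 * 3), ncol = 3), 1000,
                   subject_id = "S1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$sample_rate, 1000)
  expect_equal(back$subject_id, "S1")
  expect_equal(back$channel_ids, rec$channel_ids)
  cues <- data.frame(onset_s = c(3, 14.3),
                     movement_label = c("Wrist Flexion", "Hand Contraction"))
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_cues_csv(cues, cpath)
  expect_equal(read_cues_csv(cpath), cues)
})

test_that("recording validates its invariants", {
  expect_error(recording(matrix(0, 10, 9)), "between 1 and 8")
  expect_error(recording(matrix(0, 10, 2), sample_rate = -1), "positive")
  expect_error(recording(matrix(0, 0, 2)), "at least one sample")
})
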
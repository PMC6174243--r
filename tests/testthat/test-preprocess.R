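fs <- 500
t60 <- (0:(60 * fs - 1)) / fs

test_that("band-pass keeps alpha, kills drift and DC", {
  s10 <- sin(2 * pi * 10 * t60)
  out <- eeg_bandpass(flat_recording(s10))$samples[, 1]
  mid <- 5000:25000
  expect_lt(abs(rms(out[mid]) / rms(s10[mid]) - 1), 0.05)

  drift <- sin(2 * pi * 0.2 * t60)
  outd <- eeg_bandpass(flat_recording(drift))$samples[, 1]
  expect_lt(20 * log10(rms(outd) / rms(drift)), -20)

  dc <- rep(1, length(t60))
  outc <- eeg_bandpass(flat_recording(dc))$samples[, 1]
  expect_lt(rms(outc[mid]), 1e-3)

  expect_error(eeg_bandpass(flat_recording(s10), low = 0), "band edges")
  expect_error(eeg_bandpass(flat_recording(s10), low = 10, high = 400),
               "band edges")
  rm(s10, drift, dc, outd, outc)
})

test_that("comb filter notches mains and harmonic, spares the alpha band", {
  mid <- 5000:25000
  s50 <- sin(2 * pi * 50 * t60)
  out50 <- eeg_comb_filter(flat_recording(s50))$samples[, 1]
  expect_lt(20 * log10(rms(out50[mid]) / rms(s50[mid])), -40)

  s100 <- sin(2 * pi * 100 * t60)
  out100 <- eeg_comb_filter(flat_recording(s100))$samples[, 1]
  expect_lt(20 * log10(rms(out100[mid]) / rms(s100[mid])), -40)

  for (f in c(8, 10.5, 13)) {
    s <- sin(2 * pi * f * t60)
    out <- eeg_comb_filter(flat_recording(s))$samples[, 1]
    expect_lt(abs(20 * log10(rms(out[mid]) / rms(s[mid]))), 1)
  }

  zero <- eeg_comb_filter(flat_recording(rep(0, length(t60))))$samples
  expect_equal(max(abs(zero)), 0)

  expect_error(eeg_comb_filter(flat_recording(s50), line_freq = 300),
               "Nyquist")
})

test_that("filters are linear operators", {
  set.seed(2)
  x <- rnorm(10 * fs)
  y <- sin(2 * pi * 7 * (0:(10 * fs - 1)) / fs)
  a <- 2.5; b <- -1.3
  for (flt in list(function(r) eeg_bandpass(r),
                   function(r) eeg_comb_filter(r))) {
    fx <- flt(flat_recording(x))$samples[, 1]
    fy <- flt(flat_recording(y))$samples[, 1]
    fxy <- flt(flat_recording(a * x + b * y))$samples[, 1]
    expect_lt(max(abs(fxy - (a * fx + b * fy))), 1e-9 * max(abs(fxy)))
  }
})

test_that("bad-channel detection flags injected noise and nothing else", {
  set.seed(3)
  base <- rnorm(10 * fs)
  x <- matrix(rep(base, 10), ncol = 10)          # identical channels
  expect_identical(detect_bad_channels(flat_recording(x)), character(0))

  x[, 7] <- rnorm(10 * fs, sd = 10)              # 100x variance on O1
  expect_identical(detect_bad_channels(flat_recording(x)), "O1")

  # independent channels, one with injected variance: the outlier is
  # always caught (the strict rule may flag others near the SE bound)
  x2 <- matrix(rnorm(10 * fs * 10), ncol = 10)
  x2[, 3] <- x2[, 3] * 10
  expect_true("F7" %in% detect_bad_channels(flat_recording(x2)))

  expect_error(detect_bad_channels(flat_recording(x), threshold_se = 0),
               "positive")
  small <- flat_recording(x[, 1:3, drop = FALSE])
  expect_error(detect_bad_channels(small), "at least 4")
})

test_that("spherical splines reproduce constants and mirror symmetry", {
  n <- 500
  const <- flat_recording(matrix(7.5, n, 10))
  out <- spline_interpolate(const, c("O1", "C3"))
  expect_lt(max(abs(out$samples - 7.5)), 1e-6)

  # empty bad list returns the input untouched
  set.seed(4)
  rec <- flat_recording(matrix(rnorm(n * 10), n, 10))
  expect_identical(spline_interpolate(rec, character(0)), rec)

  # mirror-symmetric smooth field (no odd left/right dependence)
  m <- standard_montage()
  field <- 1 + 0.6 * m$y + 0.4 * m$z
  sym <- flat_recording(matrix(rep(field, each = n), n, 10))
  out2 <- spline_interpolate(sym, "O1")
  o1 <- out2$samples[1, "O1"]; o2 <- out2$samples[1, "O2"]
  expect_lt(abs(o1 - o2) / abs(o2), 0.02)

  expect_error(spline_interpolate(rec, m$label[1:7]), "at least 4 good")
  expect_error(spline_interpolate(rec, "PZ"), "not in the recording")
})

test_that("leave-one-out spline error on posterior channels is modest", {
  n <- 10
  m <- standard_montage()
  field <- 1.2 + 0.8 * m$y - 0.5 * m$z + 0.3 * m$x
  rec <- flat_recording(matrix(rep(field, each = n), n, 10))
  for (ch in c("O1", "O2", "T5", "T6")) {
    est <- spline_interpolate(rec, ch)$samples[1, ch]
    truth <- field[m$label == ch]
    expect_lt(abs(est - truth) / abs(truth), 0.15)
  }
})

test_that("condition segmentation parses, trims and conserves time", {
  ann <- tibble::tibble(
    label = c("EC", "EO", "EC", "EO", "EC", "EO"),
    onset = c(0, 60, 70, 80, 90, 100),
    duration = c(60, 10, 10, 10, 10, 10))
  rec <- flat_recording(matrix(0, 110 * fs, 10), annotations = ann)
  segs <- segment_conditions(rec)
  expect_equal(sum(segs$condition == "EC"), 3)
  expect_equal(sum(segs$condition == "EO"), 3)
  expect_equal(sum((segs$end - segs$start)[segs$condition == "EC"]), 80)
  expect_equal(sum((segs$end - segs$start)[segs$condition == "EO"]), 30)
  expect_lte(sum(segs$end - segs$start), nrow(rec$samples) / rec$rate)

  # sub-window remainders are trimmed; short segments dropped
  ann2 <- tibble::tibble(label = c("EC", "EC", "EO"),
                         onset = c(0, 10, 20), duration = c(5.7, 0.6, 3))
  rec2 <- flat_recording(matrix(0, 30 * fs, 10), annotations = ann2)
  segs2 <- segment_conditions(rec2)
  expect_equal(segs2$end[segs2$condition == "EC"] -
                 segs2$start[segs2$condition == "EC"], 5)
  expect_equal(nrow(segs2), 2)

  # case-insensitive clinical labels
  ann3 <- tibble::tibble(label = c("Eyes Closed", "eyes open"),
                         onset = c(0, 10), duration = c(10, 10))
  rec3 <- flat_recording(matrix(0, 20 * fs, 10), annotations = ann3)
  expect_equal(nrow(segment_conditions(rec3)), 2)

  expect_error(segment_conditions(flat_recording(matrix(0, fs, 10))),
               class = "alphanorm_no_conditions")
})
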
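test_that("low-pass filter matches its analytic frequency response", {
  fs <- 100
  expect_equal(lowpass(rep(7, 1000), fs), rep(7, 1000), tolerance = 1e-9)

  tt <- (0:(20 * fs - 1)) / fs
  mid <- (5 * fs):(15 * fs)        # away from edge transients
  y1 <- lowpass(sin(2 * pi * 1 * tt), fs)
  expect_equal(max(abs(y1[mid])), butter2_gain(1), tolerance = 0.01)

  y25 <- lowpass(sin(2 * pi * 25 * tt), fs)
  att_db <- -20 * log10(max(abs(y25[mid])))
  expect_gt(att_db, 20)
  expect_equal(max(abs(y25[mid])), butter2_gain(25), tolerance = 0.2)

  expect_error(lowpass(rnorm(10), fs), "warm-up")
  expect_error(lowpass(c(1, NA, rep(0, 100)), fs), "NA")
})

test_that("filtering is idempotent in the passband", {
  fs <- 100
  tt <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 1 * tt) + 0.5 * sin(2 * pi * 2.3 * tt)
  once <- lowpass(x, fs)
  twice <- lowpass(once, fs)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(twice - once) / rms(once), 0.01)
})

test_that("mid-swing peaks are found at bump centres", {
  fs <- 100
  expect_identical(detect_midswing(numeric(500), fs), integer(0))

  x <- numeric(500)
  for (c0 in c(100, 200, 300)) {
    x <- x + 100 * exp(-((seq_len(500) - 1 - c0) / 5)^2 / 2)
  }
  got <- detect_midswing(x, fs)
  # oracle: per-window argmax around each bump
  oracle <- vapply(c(100, 200, 300), function(c0) {
    w <- (c0 - 30):(c0 + 30)
    w[which.max(x[w + 1])] }, numeric(1))
  expect_equal(got, as.integer(oracle))
})

test_that("close peaks are resolved by amplitude under the separation rule", {
  fs <- 100
  x <- numeric(400)
  x <- x + 80 * exp(-((seq_len(400) - 1 - 100) / 4)^2 / 2)   # smaller
  x <- x + 120 * exp(-((seq_len(400) - 1 - 130) / 4)^2 / 2)  # larger, 0.3 s away
  got <- detect_midswing(x, fs, threshold = 40)
  # brute force: among admissible peak sets respecting 0.4 s separation,
  # greedy-by-amplitude keeps only the larger bump
  expect_equal(got, 130L)
})

test_that("toe-off valleys precede the peaks they belong to", {
  fs <- 100
  x <- numeric(300)
  x <- x - 60 * exp(-((seq_len(300) - 1 - 80) / 5)^2 / 2)
  x <- x + 150 * exp(-((seq_len(300) - 1 - 100) / 4)^2 / 2)
  to <- detect_toeoff(x, 100L, fs)
  # brute-force argmin over the search window
  w <- 21:100   # 0-based 20..99 (0.8 s lookback)
  expect_equal(to, w[which.min(x[w])] - 1L)
  expect_equal(to, 80L)

  # monotone window: minimum at the window's start boundary
  ramp <- seq_len(200) / 10
  expect_equal(detect_toeoff(ramp, 150L, fs), 150L - 80L)

  # mid-swing at the trace start: stride dropped
  expect_true(is.na(detect_toeoff(c(1, 5, 1), 0L, fs)))
})

test_that("heel strike is the first non-positive sample after the peak", {
  fs <- 100
  tt <- (0:(fs - 1)) / fs
  x <- sin(2 * pi * tt)               # crest at sample 25, zero near 50
  hs <- detect_heelstrike(x, 25L)
  # oracle: direct enumeration of the first non-positive sample after crest
  oracle <- min(which(x <= 0 & seq_along(x) > 26L)) - 1L
  expect_equal(hs, oracle)
  expect_lte(abs(hs - 50L), 1L)       # analytic zero of the sine at 0.5 s

  # signal that stays positive: last stride dropped
  expect_true(is.na(detect_heelstrike(abs(x) + 1, 25L)))
})

test_that("events on a noise-free trial match ground truth to one sample", {
  cfg <- quick_cfg(8, noise_sd = noise_free)
  tr <- simulate_trial(cfg, "RED")
  for (foot in c("left", "right")) {
    sig <- trace_channel(tr[[paste0("ankle_", foot)]], "gyro_y")
    ev <- detect_gait_events(sig, FS)
    truth <- tr$truth$events[[foot]]
    expect_equal(nrow(ev), nrow(truth))
    expect_lt(max(abs(ev$midswing - truth$midswing * FS)), 1 + 1e-9)
    expect_lt(max(abs(ev$toeoff - truth$toeoff * FS)), 1 + 1e-9)
    expect_lt(max(abs(ev$heelstrike - truth$heelstrike * FS)), 1 + 1e-9)
    expect_true(all(ev$toeoff < ev$midswing & ev$midswing < ev$heelstrike))
  }
})

test_that("walking segments split at the 2 s stride-gap rule", {
  fs <- 100
  mk_ev <- function(ms_times) {
    data.frame(toeoff = round(ms_times * fs) - 20L,
               midswing = round(ms_times * fs),
               heelstrike = round(ms_times * fs) + 15L)
  }
  # strides every 1.1 s with one 3 s gap -> 2 segments
  ms <- c(seq(1, 12, by = 1.1), seq(15.9, 26, by = 1.1))
  ws <- segment_walking(mk_ev(ms), mk_ev(ms + 0.55), fs)
  expect_equal(nrow(ws), 2)
  # a 1.5 s gap does not split
  ms2 <- c(seq(1, 12, by = 1.1), seq(13.4, 24, by = 1.1))
  expect_equal(nrow(segment_walking(mk_ev(ms2), mk_ev(ms2 + 0.55), fs)), 1)
  # boundary: a 2.0 s gap between consecutive mid-swings splits, 1.9 s not
  for (gap in c(1.9, 2.0)) {
    ms3 <- c(seq(1, 6, by = 1), seq(6 + gap, 12, by = 1))
    ws3 <- segment_walking(mk_ev(ms3), mk_ev(numeric(0)), fs)
    expect_equal(nrow(ws3), if (gap >= 2) 2 else 1)
  }
  # fewer than 3 strides in a segment: discarded and counted
  ms4 <- c(seq(1, 10, by = 1.1), c(20, 21.1))
  ws4 <- segment_walking(mk_ev(ms4), mk_ev(numeric(0)), fs)
  expect_equal(nrow(ws4), 1)
  expect_equal(attr(ws4, "n_discarded"), 1L)
  # no strides at all
  expect_equal(nrow(segment_walking(mk_ev(numeric(0)), mk_ev(numeric(0)),
                                    fs)), 0)
})

test_that("segmentation recovers the simulated segment structure", {
  cfg <- quick_cfg(9, n_segments = 5, walk_duration_s = 75, turn_gap_s = 3)
  tr <- simulate_trial(cfg, "baseline")
  ev <- detect_trial_events(tr)
  expect_equal(nrow(ev$ws), 5)
  b <- tr$truth$segment_bounds
  stride_s <- 1 / cfg$cadence_hz
  expect_true(all(abs(ev$ws$start_s - b$start_s) < 1.5 * stride_s))
  expect_true(all(abs(ev$ws$end_s - b$end_s) < 1.5 * stride_s))
})
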
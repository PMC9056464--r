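test_that("a hard-limited triangle apex is restored above the clip level", {
  tt <- seq(0, 2, by = 0.01)
  tri <- 1 - abs(tt - 1) # apex 1.0 at t = 1
  clipped <- pmin(tri, 0.8)
  res <- repair_clipping(clipped, clip_run_min = 3)
  expect_equal(nrow(res$clipped_spans), 1)
  s <- res$clipped_spans[1, "start"]
  e <- res$clipped_spans[1, "end"]
  expect_gt(max(res$samples[s:e]), 0.8)
  # oracle: the same spline through the same 3 anchors per side, with the
  # documented overshoot bound applied independently
  anchors <- c((s - 3):(s - 1), (e + 1):(e + 3))
  raw <- spline(anchors, clipped[anchors], xout = s:e, method = "fmm")$y
  lo <- min(clipped[anchors])
  want <- pmin(pmax(raw, lo), 0.8 + (0.8 - lo))
  expect_equal(res$samples[s:e], want, tolerance = 1e-12)
})

test_that("short maxima and unclipped signals are left alone", {
  x <- c(0, 1, 0, 0.5, 0.2) # global max at a single sample
  res <- repair_clipping(x, clip_run_min = 3)
  expect_identical(res$samples, x)
  expect_equal(nrow(res$clipped_spans), 0)

  sine <- sin(seq(0, 10, by = 0.01))
  expect_identical(repair_clipping(sine)$samples, sine)
})

test_that("repair never alters samples outside the reported spans", {
  tt <- seq(0, 5, by = 0.01)
  x <- pmin(sin(2 * pi * tt), 0.9)
  res <- repair_clipping(x)
  expect_gt(nrow(res$clipped_spans), 0)
  inside <- unlist(apply(res$clipped_spans, 1, function(sp) sp[1]:sp[2]))
  outside <- setdiff(seq_along(x), inside)
  expect_identical(res$samples[outside], x[outside])
})

test_that("edge-touching clipped runs are handled conservatively", {
  # a run covering the whole signal cannot be anchored at all
  expect_error(repair_clipping(rep(5, 10), clip_run_min = 3), "anchor")
  # a run touching one end has no anchors on that side: left unrepaired
  x <- c(5, 5, 5, 1, 2)
  res <- repair_clipping(x, clip_run_min = 3)
  expect_identical(res$samples, x)
  expect_equal(nrow(res$clipped_spans), 0)
})

test_that("peak detection recovers a clean 60 bpm pulse train", {
  sim <- synth_ppg(synth_config(duration_s = 60, hr_bpm = 60,
                                fm_depth = 0, am_depth = 0, noise_sd = 0,
                                wander_amp = 0, seed = 2))
  y <- enhance_peaks(bandpass(sim$record$samples, 125, 0.5, 3.5))
  peaks <- detect_peaks(y, 125)
  expect_gte(length(peaks), 59)
  expect_lte(length(peaks), 61)
})

test_that("a constant signal is a detection failure, not an error", {
  expect_null(detect_peaks(rep(1, 1000), 125))
})

test_that("a plateau maximum resolves to its earliest index", {
  x <- rep(0, 400)
  x[100:110] <- 5 # single flat-topped ROI
  x[300] <- 4
  cfg <- peak_detect_config(ma_window_s = 0.4, bpm_min = 10, bpm_max = 300)
  peaks <- detect_peaks(x, 125, cfg)
  expect_true(100 %in% peaks)
  expect_false(any(peaks %in% 101:110))
})

test_that("detected beats match generator truth across heart rates", {
  for (hr in c(50, 70, 90, 110)) {
    sim <- synth_ppg(synth_config(duration_s = 60, hr_bpm = hr,
                                  noise_sd = 0.02, seed = 50 + hr))
    y <- enhance_peaks(bandpass(sim$record$samples, 125, 0.5, 3.5))
    peaks <- reject_false_peaks(detect_peaks(y, 125), 125)
    peak_t <- (peaks - 1) / 125
    true_t <- sim$truth$beat_times + sim$truth$pulse_peak_offset_s
    hit <- vapply(true_t, function(t0) any(abs(peak_t - t0) <= 0.040),
                  logical(1))
    expect_gte(mean(hit), 0.95)
  }
})

test_that("an interval below 30% of the mean marks a false peak", {
  fs <- 100
  p <- c(seq(0, 900, by = 100), 512) # extra peak 0.12 s after a true one
  p <- sort(p)
  out <- reject_false_peaks(p, fs)
  expect_identical(out, as.double(seq(0, 900, by = 100)))
  regular <- seq(0, 900, by = 100)
  expect_identical(reject_false_peaks(regular, fs), as.double(regular))
})

test_that("false-peak rejection matches the brute-force oracle", {
  withr::with_seed(61, {
    for (rep in 1:30) {
      true_p <- cumsum(c(0, round(runif(30, 80, 120))))
      extra <- true_p[sample(29, 4)] + round(runif(4, 5, 25))
      p <- sort(unique(c(true_p, extra)))
      got <- reject_false_peaks(p, 100)
      want <- oracle_reject(as.double(p))
      expect_identical(got, want)
      # idempotence
      expect_identical(reject_false_peaks(got, 100), got)
    }
  })
})

test_that("RR intervals and heart rate follow their definitions", {
  rr <- rr_series(c(0, 125, 250), fs = 125)
  expect_equal(rr$rr_ms, c(1000, 1000))
  expect_equal(rr_series(c(0, 100), fs = 125)$rr_ms, 800)
  expect_error(rr_series(c(100, 100, 200), fs = 125), "increasing")
  expect_error(rr_series(5, fs = 125), "2 peaks")

  expect_equal(heart_rate_bpm(rr), 60)
  expect_equal(heart_rate_bpm(rr_series(c(0, 62.5), 125)), 120)
  rr2 <- rr_series(c(0, 750, 1600) / 1000 * 125, fs = 125)
  expect_equal(heart_rate_bpm(rr2), 60000 / 800) # intervals 750, 850 ms
})

test_that("missed-beat gaps are subdivided onto the beat grid", {
  p <- c(0, 100, 200, 400, 500, 600) # one dropped beat at 300
  out <- fill_missed_beats(p, 100)
  expect_equal(out, c(0, 100, 200, 300, 400, 500, 600))
  # regular trains and disabled correction pass through unchanged
  expect_equal(fill_missed_beats(p, 100, gap_factor = Inf), as.double(p))
  reg <- seq(0, 1000, by = 100)
  expect_equal(fill_missed_beats(reg, 100), as.double(reg))
})
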
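test_that("ground-truth rate is the respiratory frequency times 60", {
  sim <- synth_ppg(synth_config(duration_s = 30, resp_hz = 0.25, seed = 3))
  expect_identical(sim$truth$resp_brpm, 0.25 * 60)
})

test_that("without modulation the beat train is perfectly regular", {
  sim <- synth_ppg(synth_config(duration_s = 60, hr_bpm = 75, fm_depth = 0,
                                am_depth = 0, noise_sd = 0, seed = 5))
  ivs <- diff(sim$truth$beat_times)
  expect_gte(length(ivs), 73) # ~75 beats in 60 s, boundary beat may vary
  expect_equal(ivs, rep(60 / 75, length(ivs)), tolerance = 1e-9)
})

test_that("the same seed reproduces the record bit for bit", {
  cfg <- synth_config(duration_s = 60, spike_rate = 3, dropout_rate = 2,
                      clip_quantile = 0.95, seed = 99)
  a <- synth_ppg(cfg)
  b <- synth_ppg(cfg)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$truth, b$truth)
})

test_that("a too-short duration is refused", {
  expect_error(synth_ppg(synth_config(duration_s = 1, hr_bpm = 40)),
               "2 beats")
})

test_that("rendered pulse count matches the configured heart rate", {
  for (hr in c(55, 70, 90)) {
    sim <- synth_ppg(synth_config(duration_s = 60, hr_bpm = hr,
                                  noise_sd = 0, wander_amp = 0,
                                  seed = hr))
    x <- sim$record$samples
    n_max <- sum(diff(sign(diff(x))) == -2 &
                   x[2:(length(x) - 1)] > 0.5)
    expect_gte(n_max, hr - 1)
    expect_lte(n_max, hr + 1)
  }
})

test_that("the generated RR sequence is modulated at the set frequency", {
  sim <- synth_ppg(synth_config(duration_s = 240, resp_hz = 0.3,
                                fm_depth = 0.05, noise_sd = 0, seed = 8))
  rr <- diff(sim$truth$beat_times)
  tt <- sim$truth$beat_times[-1]
  grid <- seq(tt[1], tt[length(tt)], by = 0.25)
  y <- spline(tt, rr, xout = grid)$y
  y <- y - mean(y)
  spec <- Mod(fft(y))^2
  freqs <- (seq_along(spec) - 1) * 4 / length(spec)
  in_band <- freqs >= 0.1 & freqs <= 0.4
  f_peak <- freqs[in_band][which.max(spec[in_band])]
  expect_lt(abs(f_peak - 0.3), 4 / length(spec) * 1.5 + 1e-9)
})

test_that("NaN fraction tracks the dropout configuration", {
  cfg <- synth_config(duration_s = 600, dropout_rate = 2,
                      dropout_len_s = 1, seed = 17)
  sim <- synth_ppg(cfg)
  expected <- 2 * 10 * 1 * 125 # runs * minutes * len_s * fs
  got <- sum(is.na(sim$record$samples))
  expect_gt(got, 0.6 * expected)
  expect_lt(got, 1.4 * expected)
})

test_that("the fixture suite is complete and reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  suite1 <- make_fixture_suite(dir1, duration_s = 30)
  suite2 <- make_fixture_suite(dir2, duration_s = 30)
  expect_gte(nrow(suite1), 10)
  expect_true(all(file.exists(suite1$signal_file)))
  expect_true(all(file.exists(suite1$truth_file)))
  expect_true(all(suite1$resp_brpm >= 8 & suite1$resp_brpm <= 23))
  for (i in seq_len(nrow(suite1))) {
    expect_identical(readLines(suite1$signal_file[i]),
                     readLines(suite2$signal_file[i]))
  }
  rec <- read_ppg_csv(suite1$signal_file[1])
  expect_equal(rec$fs, 125, tolerance = 1e-6)
})
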
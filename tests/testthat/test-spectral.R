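test_that("a constant RR series resamples to zeros", {
  rr <- rr_series(seq(0, 1250, by = 125), fs = 125) # 1000 ms intervals
  res <- resample_rr(rr, 4)
  expect_equal(res$series, rep(0, length(res$series)), tolerance = 1e-9)
  expect_equal(res$fs, 4)
})

test_that("too few intervals is an estimation failure", {
  expect_error(resample_rr(rr_series(c(0, 100, 200, 300), 125), 4),
               "at least 4")
})

test_that("a sinusoidally modulated RR series keeps its frequency", {
  # beats at ~1 Hz whose intervals oscillate at 0.25 Hz
  t_k <- 0
  repeat {
    t_last <- t_k[length(t_k)]
    iv <- 1 * (1 + 0.05 * sin(2 * pi * 0.25 * t_last))
    if (t_last + iv > 120) break
    t_k <- c(t_k, t_last + iv)
  }
  rr <- rr_series(round(t_k * 125), fs = 125)
  res <- resample_rr(rr, 4)
  spec <- welch_psd(res$series, res$fs)
  f_peak <- spec$freqs[which.max(spec$psd)]
  expect_lt(abs(f_peak - 0.25), 0.02)
})

test_that("a single segment reproduces the direct Hann periodogram", {
  withr::with_seed(71, x <- rnorm(200))
  cfg <- welch_config(nperseg_fraction = 1)
  got <- welch_psd(x, 4, cfg)
  want <- oracle_periodogram(x, 4, nfft = 256)
  expect_equal(got$freqs, want$freqs, tolerance = 1e-12)
  expect_equal(got$psd, want$psd, tolerance = 1e-9)
})

test_that("the PSD integrates to the white-noise variance (Parseval)", {
  withr::with_seed(73, x <- rnorm(4096, sd = 2))
  spec <- welch_psd(x, 8, welch_config())
  df <- diff(spec$freqs[1:2])
  total <- sum(spec$psd) * df
  expect_gt(total, 0.9 * 4)
  expect_lt(total, 1.1 * 4)
})

test_that("a pure tone lands in the right PSD bin", {
  tt <- seq(0, 200, by = 1 / 4)
  x <- sin(2 * pi * 0.3 * tt)
  spec <- welch_psd(x, 4)
  f_peak <- spec$freqs[which.max(spec$psd)]
  expect_lt(abs(f_peak - 0.3), diff(spec$freqs[1:2]) + 1e-12)
})

test_that("the estimate is invariant to a constant offset", {
  withr::with_seed(79, x <- rnorm(512))
  a <- welch_psd(x, 4)
  b <- welch_psd(x + 42, 4)
  expect_equal(a$psd, b$psd, tolerance = 1e-9)
})

test_that("too-short series are estimation failures", {
  expect_error(welch_psd(rnorm(5), 4), "too short")
})

test_that("the rate is the in-band PSD maximum times 60", {
  spec <- structure(list(freqs = c(0.1, 0.25, 0.4), psd = c(1, 5, 2)),
                    class = "spectral_estimate")
  expect_equal(respr_from_psd(spec), 15)

  # out-of-band global maximum is ignored
  spec2 <- structure(
    list(freqs = c(0.1, 0.2, 0.3, 0.5), psd = c(1, 4, 2, 100)),
    class = "spectral_estimate"
  )
  expect_equal(respr_from_psd(spec2), 12)

  # flat PSD ties resolve to the lowest in-band frequency
  spec3 <- structure(
    list(freqs = seq(0, 0.5, by = 0.05), psd = rep(1, 11)),
    class = "spectral_estimate"
  )
  expect_equal(respr_from_psd(spec3), 6)

  spec4 <- structure(list(freqs = c(0.5, 0.6), psd = c(1, 2)),
                     class = "spectral_estimate")
  expect_error(respr_from_psd(spec4), "band")
})

test_that("tidy and autoplot work on spectral estimates", {
  spec <- welch_psd(sin(2 * pi * 0.2 * seq(0, 100, 0.25)), 4)
  td <- tidy(spec)
  expect_named(td, c("freq_hz", "psd"))
  expect_equal(nrow(td), length(spec$freqs))
  expect_s3_class(autoplot(spec), "ggplot")
})
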
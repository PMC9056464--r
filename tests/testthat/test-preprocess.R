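test_that("missing samples are filled by neighbour means and linear runs", {
  expect_equal(interpolate_missing(c(1, NA, 3)), c(1, 2, 3))
  expect_equal(interpolate_missing(c(NA, 5, 5)), c(5, 5, 5))
  expect_equal(interpolate_missing(c(1, NA, NA, 4)), c(1, 2, 3, 4))
  expect_equal(interpolate_missing(c(2, 4, NA, NA)), c(2, 4, 4, 4))
  expect_error(interpolate_missing(c(NA_real_, NA_real_)), "missing")
})

test_that("interpolation is idempotent and the identity on clean input", {
  withr::with_seed(21, {
    x <- rnorm(200)
    expect_identical(interpolate_missing(x), x)
    x[sample(200, 30)] <- NA
    once <- interpolate_missing(x)
    expect_false(anyNA(once))
    expect_identical(interpolate_missing(once), once)
    expect_length(once, 200)
  })
})

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  fs <- 125
  tt <- seq(0, 120, by = 1 / fs)
  keep <- sin(2 * pi * 0.25 * tt)
  drop <- sin(2 * pi * 2.0 * tt)
  y_keep <- bandpass(keep, fs, 0.1, 0.4)
  y_drop <- bandpass(drop, fs, 0.1, 0.4)
  rms <- function(v) sqrt(mean(v^2))
  expect_gte(rms(y_keep), 0.9 * rms(keep))
  expect_lte(rms(y_drop), 0.1 * rms(drop))
  expect_equal(bandpass(numeric(1000), fs, 0.1, 0.4), numeric(1000))
})

test_that("band-pass is linear", {
  fs <- 125
  withr::with_seed(7, {
    a <- rnorm(2000)
    b <- rnorm(2000)
  })
  lhs <- bandpass(a + b, fs, 0.5, 3.5)
  rhs <- bandpass(a, fs, 0.5, 3.5) + bandpass(b, fs, 0.5, 3.5)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("band edges are validated against the sampling rate", {
  expect_error(bandpass(rnorm(100), 10, 0.4, 0.1), "band edges")
  expect_error(bandpass(rnorm(100), 10, 0.1, 6), "band edges")
  expect_error(bandpass(c(1, NA, 3), 10, 0.1, 0.4), "missing")
})

test_that("peak enhancement maps the range onto [l_lt, l_lt + rb]", {
  expect_equal(enhance_peaks(c(0, 0.5, 1), rb = 1024, l_lt = 0),
               c(0, 512, 1024))
  expect_equal(enhance_peaks(c(-3, 7), rb = 10, l_lt = 5), c(5, 15))
  expect_error(enhance_peaks(rep(2, 10)), "constant")
})

test_that("peak enhancement preserves the full sample ranking", {
  withr::with_seed(13, x <- rnorm(500))
  y <- enhance_peaks(x)
  expect_identical(order(y), order(x))
  expect_identical(which.max(y), which.max(x))
  expect_equal(cor(rank(x), rank(y)), 1)
})

test_that("a lone spike is replaced by the local median", {
  x <- c(1, 1, 1, 50, 1, 1, 1, 1)
  res <- hampel_filter(x, half_window = 3, n_sigma = 3)
  expect_equal(res$samples, rep(1, 8))
  expect_identical(res$outlier_indices, 4L)
})

test_that("a clean slow sinusoid passes the Hampel filter untouched", {
  x <- sin(2 * pi * 0.5 * seq(0, 10, by = 1 / 125))
  res <- hampel_filter(x)
  expect_identical(res$samples, x)
  expect_length(res$outlier_indices, 0)
})

test_that("hampel_filter matches the brute-force oracle on random input", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(20:200, 1)
      x <- rnorm(n)
      x[sample(n, 3)] <- x[sample(n, 3)] + 20 # inject outliers
      got <- hampel_filter(x, 3, 3)
      want <- oracle_hampel(x, 3, 3)
      expect_identical(got$samples, want$samples)
      expect_identical(got$outlier_indices, want$outlier_indices)
    }
  })
})

test_that("hampel_filter only alters the flagged indices", {
  withr::with_seed(37, x <- rnorm(300))
  x[c(50, 150)] <- 30
  res <- hampel_filter(x)
  untouched <- setdiff(seq_along(x), res$outlier_indices)
  expect_identical(res$samples[untouched], x[untouched])
})

test_that("hampel_filter refuses too-short signals", {
  expect_error(hampel_filter(c(1, 2, 3), half_window = 3), "shorter")
})
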
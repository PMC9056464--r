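# Independent brute-force oracles, written as literal loops so they stay
# structurally independent of the package implementations they check.

# Hampel variant with end-mean padding and start-truncated windows:
# for each original sample, window = sample +/- hw neighbours drawn from
# the end-padded signal; replace when |x - med| > n_sigma * 1.4826 * MAD.
oracle_hampel <- function(x, hw = 3, n_sigma = 3) {
  n <- length(x)
  padded <- c(x, rep(mean(x), hw))
  out <- x
  idx <- integer(0)
  for (i in 1:n) {
    w <- padded[max(1, i - hw):(i + hw)]
    m <- median(w)
    s <- 1.4826 * median(abs(w - m))
    if (abs(x[i] - m) > n_sigma * s) {
      out[i] <- m
      idx <- c(idx, i)
    }
  }
  list(samples = out, outlier_indices = idx)
}

# iterative false-peak removal: each pass recomputes the mean interval,
# finds the first interval below fraction * mean, drops its later peak.
oracle_reject <- function(p, fraction = 0.30) {
  repeat {
    if (length(p) < 2) return(NULL)
    iv <- diff(p)
    thr <- fraction * mean(iv)
    hit <- 0
    for (k in seq_along(iv)) {
      if (iv[k] < thr) { hit <- k; break }
    }
    if (hit == 0) return(p)
    p <- p[-(hit + 1)]
  }
}

# single Hann-tapered periodogram with segment-mean removal, one-sided
# density scaling, zero-padded to nfft
oracle_periodogram <- function(x, fs, nfft) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  seg <- (x - mean(x)) * w
  X <- fft(c(seg, rep(0, nfft - n)))
  half <- nfft %/% 2 + 1
  p <- Mod(X[1:half])^2 / (fs * sum(w^2))
  scale <- rep(2, half)
  scale[1] <- 1
  if (nfft %% 2 == 0) scale[half] <- 1
  list(freqs = (0:(half - 1)) * fs / nfft, psd = p * scale)
}

# a small clean simulated record shared by several tests
clean_sim <- function(duration_s = 120, resp_brpm = 15, hr_bpm = 70,
                      seed = 11L) {
  synth_ppg(synth_config(
    duration_s = duration_s, resp_hz = resp_brpm / 60, hr_bpm = hr_bpm,
    noise_sd = 0, wander_amp = 0, seed = seed
  ))
}
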
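#' Welch spectral-estimation configuration
#'
#' Parameters for the modified Welch estimate of the RR-interval power
#' spectral density: Hann-tapered overlapping segments, density scaling,
#' mean averaging, and an FFT zero-padded to the full series length
#' (with a floor of 256 bins, so short windows still resolve the
#' respiratory band).
#'
#' @param resample_hz Uniform resampling rate for the RR series
#'   (default 4 Hz; comfortably above twice the 0.4 Hz band edge).
#' @param overlap_fraction Segment overlap (default 0.5).
#' @param nperseg_fraction Segment length as a fraction of the series
#'   length (default 0.5, giving 3 half-overlapping segments).
#' @param nfft_min Zero-padding floor for the FFT length (default 256).
#' @param band_low_hz,band_high_hz Respiratory search band in Hz
#'   (defaults 0.1 and 0.4, i.e. 6-24 breaths/min).
#' @return A `welch_config` list.
#' @export
welch_config <- function(resample_hz = 4, overlap_fraction = 0.5,
                         nperseg_fraction = 0.5, nfft_min = 256,
                         band_low_hz = 0.1, band_high_hz = 0.4) {
  stopifnot(resample_hz > 0, overlap_fraction > 0, overlap_fraction < 1,
            nperseg_fraction > 0, nperseg_fraction <= 1,
            band_low_hz > 0, band_high_hz > band_low_hz)
  structure(
    list(resample_hz = resample_hz, overlap_fraction = overlap_fraction,
         nperseg_fraction = nperseg_fraction, nfft_min = nfft_min,
         band_low_hz = band_low_hz, band_high_hz = band_high_hz),
    class = "welch_config"
  )
}

#' Resample an RR series onto a uniform grid
#'
#' The inter-beat intervals form an irregularly spaced series (one value
#' per beat). Each interval is placed at its cumulative-time position
#' (the time of the beat that closes it), cubic-spline interpolated onto
#' a uniform grid at `resample_hz`, and mean-centred so the spectral
#' estimate is not dominated by the DC component.
#'
#' @param rr An [rr_series()] with at least 4 intervals.
#' @param resample_hz Grid rate in Hz (default 4).
#' @return List with `series` (mean-removed uniform samples, in ms about
#'   zero) and `fs` (`resample_hz`).
#' @export
resample_rr <- function(rr, resample_hz = 4) {
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr$rr_ms) < 4) {
    stop("need at least 4 RR intervals for spectral estimation",
         call. = FALSE)
  }
  t_beat <- cumsum(rr$rr_ms) / 1000 # time of each interval's closing beat
  grid <- seq(t_beat[1], t_beat[length(t_beat)], by = 1 / resample_hz)
  y <- stats::spline(t_beat, rr$rr_ms, xout = grid, method = "fmm")$y
  list(series = y - mean(y), fs = resample_hz)
}

#' Welch power spectral density
#'
#' Splits the series into `nperseg_fraction`-length segments with
#' `overlap_fraction` overlap, removes each segment's mean, applies a
#' Hann taper, zero-pads the FFT to the full series length (floored at
#' `nfft_min`), scales each periodogram as a one-sided density
#' (normalised by the taper power), and averages the periodograms.
#'
#' @param series Uniformly sampled numeric series, length >= 8.
#' @param fs Sampling rate of `series` in Hz.
#' @param cfg A [welch_config()].
#' @return A `spectral_estimate`: list with `freqs` (Hz, ascending from 0
#'   to `fs/2`) and `psd` (power density, same length).
#' @export
welch_psd <- function(series, fs, cfg = welch_config()) {
  x <- as.double(series)
  n <- length(x)
  if (n < 8) stop("series too short for Welch estimation", call. = FALSE)
  nperseg <- max(8L, round(cfg$nperseg_fraction * n))
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg - floor(cfg$overlap_fraction * nperseg))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  nfft <- max(n, cfg$nfft_min)

  taper <- .hann(nperseg)
  norm <- fs * sum(taper^2)
  n_half <- nfft %/% 2 + 1L

  acc <- numeric(n_half)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * taper
    spec <- stats::fft(c(seg, numeric(nfft - nperseg)))[seq_len(n_half)]
    p <- Mod(spec)^2 / norm
    # one-sided: double everything except DC (and Nyquist when nfft even)
    dbl <- rep(2, n_half)
    dbl[1] <- 1
    if (nfft %% 2 == 0) dbl[n_half] <- 1
    acc <- acc + p * dbl
  }
  structure(
    list(freqs = (seq_len(n_half) - 1) * fs / nfft,
         psd = acc / length(starts)),
    class = "spectral_estimate"
  )
}

# periodic Hann taper (matches the DFT periodicity convention)
.hann <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Respiratory rate from a power spectral density
#'
#' The respiratory rate is the frequency of the PSD maximum restricted to
#' the respiratory band, converted to breaths per minute. Ties go to the
#' lowest frequency (the physiologically slower rate). By construction
#' the result lies in `[band_low_hz, band_high_hz] * 60`.
#'
#' @param spec A `spectral_estimate` from [welch_psd()].
#' @param band_low_hz,band_high_hz Search band in Hz (defaults 0.1, 0.4).
#' @return Respiratory rate in breaths per minute.
#' @examples
#' spec <- structure(list(freqs = c(0.1, 0.25, 0.4), psd = c(1, 5, 2)),
#'                   class = "spectral_estimate")
#' respr_from_psd(spec) # 15
#' @export
respr_from_psd <- function(spec, band_low_hz = 0.1, band_high_hz = 0.4) {
  in_band <- which(spec$freqs >= band_low_hz & spec$freqs <= band_high_hz)
  if (length(in_band) == 0) {
    stop("PSD has no bins inside the respiratory band", call. = FALSE)
  }
  f_star <- spec$freqs[in_band][which.max(spec$psd[in_band])]
  f_star * 60
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d bins, 0-%.3g Hz\n",
              length(x$freqs), max(x$freqs)))
  invisible(x)
}
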
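#' Fill missing PPG samples by interpolation
#'
#' Replaces every missing (`NA`/NaN) sample: an isolated gap becomes the
#' mean of its two neighbours, runs of consecutive missing samples are
#' filled by linear interpolation between the bounding values, and runs
#' touching either end of the signal take the nearest observed value.
#' Length is unchanged and the result contains no missing values.
#'
#' @param samples Numeric vector, possibly with `NA`/NaN.
#' @return Numeric vector of the same length with no missing values.
#' @examples
#' interpolate_missing(c(1, NA, 3)) # 1 2 3
#' @export
interpolate_missing <- function(samples) {
  samples[is.nan(samples)] <- NA_real_
  if (all(is.na(samples))) {
    stop("all samples are missing; nothing to interpolate", call. = FALSE)
  }
  if (!anyNA(samples)) return(as.double(samples))
  as.double(zoo::na.approx(samples, na.rm = FALSE, rule = 2))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward (zero phase), so
#' peak positions do not shift. Used with the respiratory band
#' (0.1-0.4 Hz) to extract the breathing waveform and with a cardiac band
#' (0.5-3.5 Hz) ahead of systolic-peak detection.
#'
#' @param samples Numeric vector without missing values.
#' @param fs Sampling frequency in Hz.
#' @param low_hz,high_hz Band edges in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth order per pass (default 2; the effective
#'   forward-backward order is twice that).
#' @return Filtered vector, same length.
#' @export
bandpass <- function(samples, fs, low_hz = 0.1, high_hz = 0.4, order = 2) {
  if (anyNA(samples)) {
    stop("`samples` must not contain missing values; interpolate first",
         call. = FALSE)
  }
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  as.double(signal::filtfilt(bf, as.double(samples)))
}

#' Peak enhancement by range scaling
#'
#' Rescales the signal linearly onto `[l_lt, l_lt + rb]`:
#' `rb * (x - min(x)) / range(x) + l_lt`. The map is strictly
#' order-preserving, so peak locations are untouched while the dynamic
#' range becomes fixed and large, which stabilises the moving-average
#' threshold used by peak detection.
#'
#' @param samples Numeric vector with `max(x) > min(x)`.
#' @param rb Output range (default 1024).
#' @param l_lt Output lower limit (default 0).
#' @return Rescaled vector: minimum `l_lt`, maximum `l_lt + rb`.
#' @examples
#' enhance_peaks(c(0, 0.5, 1)) # 0 512 1024
#' @export
enhance_peaks <- function(samples, rb = 1024, l_lt = 0) {
  if (anyNA(samples)) stop("`samples` must not contain missing values",
                           call. = FALSE)
  rng <- max(samples) - min(samples)
  if (rng <= 0) {
    stop("constant signal: range is zero, cannot enhance", call. = FALSE)
  }
  rb * (samples - min(samples)) / rng + l_lt
}

#' Hampel outlier filter with mean end-padding
#'
#' Sliding-window outlier rejection: for each sample, the window is the
#' sample plus `half_window` neighbours per side; a robust spread is
#' formed from the window's median absolute deviation
#' (`sigma = 1.4826 * MAD`) and samples deviating from the window median
#' by more than `n_sigma * sigma` are replaced by that median. The signal
#' is first extended at its end by `half_window` copies of the overall
#' signal mean so the final samples still sit in full windows; at the
#' start the window is simply truncated. Replacement is non-recursive:
#' every window is drawn from the original (padded) signal.
#'
#' @param samples Numeric vector without missing values, longer than
#'   `2 * half_window`.
#' @param half_window Neighbours per side (default 3, i.e. a 7-point
#'   window).
#' @param n_sigma Rejection threshold in robust standard deviations
#'   (default 3).
#' @return A list with `samples` (filtered, same length) and
#'   `outlier_indices` (1-based positions that were replaced).
#' @export
hampel_filter <- function(samples, half_window = 3, n_sigma = 3) {
  if (anyNA(samples)) stop("`samples` must not contain missing values",
                           call. = FALSE)
  n <- length(samples)
  hw <- as.integer(half_window)
  if (n <= 2 * hw) {
    stop("signal shorter than one Hampel window", call. = FALSE)
  }
  padded <- c(as.double(samples), rep(mean(samples), hw))

  # sliding windows over the padded signal; start-edge windows truncated
  med <- numeric(n)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    w <- padded[max(1L, i - hw):(i + hw)]
    med[i] <- stats::median(w)
    sigma[i] <- 1.4826 * stats::median(abs(w - med[i]))
  }
  out_idx <- which(abs(samples - med) > n_sigma * sigma)
  filtered <- as.double(samples)
  filtered[out_idx] <- med[out_idx]
  list(samples = filtered, outlier_indices = out_idx)
}
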
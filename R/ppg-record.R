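#' Construct a PPG record
#'
#' A `ppg_record` bundles a sampled photoplethysmogram with its sampling
#' rate and, optionally, a reference respiratory-rate series (as recorded
#' by a bedside monitor at 1 Hz, for example). Missing samples are
#' represented by `NA`; every unparseable or empty cell read from disk and
#' every IEEE NaN is mapped onto this single marker.
#'
#' @param samples Numeric vector of PPG samples in sensor units. `NA`/NaN
#'   mark missing samples.
#' @param fs Sampling frequency in Hz (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#' @param subject_id Optional opaque subject label.
#' @param ref_resp Optional reference respiratory rates: a data frame with
#'   columns `time_s` (strictly increasing) and `resp_brpm`.
#'
#' @return An object of class `ppg_record`: a list with elements
#'   `samples`, `fs`, `start_time`, `subject_id` and `ref_resp` (a tibble,
#'   possibly empty).
#' @examples
#' rec <- ppg_record(sin(2 * pi * 1.2 * seq(0, 10, by = 1 / 125)), fs = 125)
#' rec
#' @export
ppg_record <- function(samples, fs, start_time = 0, subject_id = NULL,
                       ref_resp = NULL) {
  samples <- as.double(samples)
  samples[is.nan(samples)] <- NA_real_
  if (length(samples) < 1) {
    stop("`samples` must contain at least one value", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (is.null(ref_resp)) {
    ref_resp <- tibble::tibble(time_s = double(), resp_brpm = double())
  } else {
    ref_resp <- tibble::as_tibble(ref_resp)
    if (!all(c("time_s", "resp_brpm") %in% names(ref_resp))) {
      stop("`ref_resp` needs columns `time_s` and `resp_brpm`", call. = FALSE)
    }
    if (nrow(ref_resp) > 1 && any(diff(ref_resp$time_s) <= 0)) {
      stop("`ref_resp$time_s` must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(
      samples = samples, fs = as.double(fs),
      start_time = as.double(start_time),
      subject_id = subject_id, ref_resp = ref_resp
    ),
    class = "ppg_record"
  )
}

#' @export
print.ppg_record <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf(
    "<ppg_record> %d samples @ %g Hz (%.1f s)%s\n",
    length(x$samples), x$fs, dur,
    if (is.null(x$subject_id)) "" else paste0(" [", x$subject_id, "]")
  ))
  n_na <- sum(is.na(x$samples))
  if (n_na > 0) cat(sprintf("  missing samples: %d\n", n_na))
  if (nrow(x$ref_resp) > 0) {
    cat(sprintf(
      "  reference rates: %d values, %.1f-%.1f brpm\n",
      nrow(x$ref_resp), min(x$ref_resp$resp_brpm), max(x$ref_resp$resp_brpm)
    ))
  }
  invisible(x)
}

#' @export
length.ppg_record <- function(x) length(x$samples)

#' Duration of a PPG record in seconds
#' @param record A [ppg_record()].
#' @return Duration in seconds.
#' @export
ppg_duration <- function(record) length(record$samples) / record$fs

#' Inter-beat interval series from peak indices
#'
#' Converts strictly increasing systolic-peak sample indices into the
#' series of inter-beat (RR) intervals, in milliseconds.
#'
#' @param peak_indices Strictly increasing 0-based sample indices of
#'   detected peaks (at least 2).
#' @param fs Sampling frequency in Hz.
#' @return An `rr_series` object: list with `peak_indices`, `rr_ms`
#'   (length `length(peak_indices) - 1`) and `fs`.
#' @examples
#' rr_series(c(0, 125, 250), fs = 125)$rr_ms # 1000 1000
#' @export
rr_series <- function(peak_indices, fs) {
  peak_indices <- as.double(peak_indices)
  if (length(peak_indices) < 2) {
    stop("need at least 2 peaks to form RR intervals", call. = FALSE)
  }
  if (any(diff(peak_indices) <= 0)) {
    stop("`peak_indices` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      peak_indices = peak_indices,
      rr_ms = diff(peak_indices) / fs * 1000,
      fs = fs
    ),
    class = "rr_series"
  )
}

#' Mean heart rate from an RR series
#'
#' @param rr An [rr_series()].
#' @return Heart rate in beats per minute, `60000 / mean(rr_ms)`.
#' @examples
#' heart_rate_bpm(rr_series(c(0, 125, 250), fs = 125)) # 60
#' @export
heart_rate_bpm <- function(rr) {
  if (!inherits(rr, "rr_series") || length(rr$rr_ms) < 1) {
    stop("`rr` must be an rr_series with at least one interval", call. = FALSE)
  }
  60000 / mean(rr$rr_ms)
}
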
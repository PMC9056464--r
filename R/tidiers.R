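#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a spectral estimate into a tibble
#'
#' @param x A `spectral_estimate` from [welch_psd()].
#' @param ... Unused.
#' @return Tibble with columns `freq_hz` and `psd`.
#' @method tidy spectral_estimate
#' @export
tidy.spectral_estimate <- function(x, ...) {
  tibble::tibble(freq_hz = x$freqs, psd = x$psd)
}

#' Tidy an RR series into a tibble
#'
#' @param x An [rr_series()].
#' @param ... Unused.
#' @return Tibble with `beat_time_s` (time of each interval's closing
#'   beat) and `rr_ms`.
#' @method tidy rr_series
#' @export
tidy.rr_series <- function(x, ...) {
  tibble::tibble(
    beat_time_s = x$peak_indices[-1] / x$fs,
    rr_ms = x$rr_ms
  )
}

#' One-row summary of a windowed estimation run
#'
#' @param x A `respyre_estimates` tibble from [estimate_record()].
#' @param ... Unused.
#' @return Tibble with `n_windows`, `n_skipped`, `n_clamped`,
#'   `mean_respr`, `sd_respr`, `mean_hr_bpm`, `window_s`, and (when the
#'   record carried reference rates) `mae` and `rmse`.
#' @method glance respyre_estimates
#' @export
glance.respyre_estimates <- function(x, ...) {
  ok <- !x$skipped
  out <- tibble::tibble(
    n_windows = nrow(x),
    n_skipped = sum(x$skipped),
    n_clamped = sum(x$clamped[ok], na.rm = TRUE),
    mean_respr = if (any(ok)) mean(x$respr[ok]) else NA_real_,
    sd_respr = if (sum(ok) > 1) stats::sd(x$respr[ok]) else NA_real_,
    mean_hr_bpm = if (any(ok)) mean(x$hr_bpm[ok]) else NA_real_,
    window_s = x$window_s[1]
  )
  ref <- attr(x, "ref_resp")
  if (!is.null(ref) && nrow(ref) > 0 && any(ok)) {
    ev <- tryCatch(evaluate_estimates(x), error = function(e) NULL)
    if (!is.null(ev)) {
      out$mae <- ev$mae
      out$rmse <- ev$rmse
    }
  }
  out
}
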
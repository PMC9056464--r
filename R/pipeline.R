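#' Full pipeline configuration
#'
#' Bundles the per-stage configurations together with the windowing and
#' gating choices. Ablation switches (`use_interp`, `use_hampel`,
#' `use_clip_repair`) exist so the contribution of each artefact-handling
#' stage can be measured; all default to on. With `use_interp = FALSE`
#' missing samples are replaced by zeros instead of being interpolated.
#'
#' @param window_s Analysis window length in seconds (default 90, the
#'   size at which windowed estimation error bottoms out on stationary
#'   signals).
#' @param use_esqi Gate windows on the entropy signal-quality index.
#' @param band_low_hz,band_high_hz Respiratory band edges, Hz.
#' @param cardiac_low_hz,cardiac_high_hz Cardiac band edges, Hz; peak
#'   detection runs on this band because the respiratory band contains
#'   no cardiac peaks.
#' @param filter_order Butterworth order per pass.
#' @param rb,l_lt Peak-enhancement range and lower limit.
#' @param hampel_half_window,hampel_n_sigma Hampel filter parameters.
#' @param peaks A [peak_detect_config()].
#' @param welch A [welch_config()].
#' @param scaling A [scaling_config()].
#' @param use_interp,use_hampel,use_clip_repair Ablation switches.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_s = 90, use_esqi = TRUE,
                            band_low_hz = 0.1, band_high_hz = 0.4,
                            cardiac_low_hz = 0.5, cardiac_high_hz = 3.5,
                            filter_order = 2, rb = 1024, l_lt = 0,
                            hampel_half_window = 3, hampel_n_sigma = 3,
                            peaks = peak_detect_config(),
                            welch = welch_config(band_low_hz = band_low_hz,
                                                 band_high_hz = band_high_hz),
                            scaling = scaling_config(),
                            use_interp = TRUE, use_hampel = TRUE,
                            use_clip_repair = TRUE) {
  stopifnot(window_s > 0, band_low_hz > 0, band_high_hz > band_low_hz,
            cardiac_low_hz > 0, cardiac_high_hz > cardiac_low_hz)
  structure(
    list(window_s = window_s, use_esqi = use_esqi,
         band_low_hz = band_low_hz, band_high_hz = band_high_hz,
         cardiac_low_hz = cardiac_low_hz, cardiac_high_hz = cardiac_high_hz,
         filter_order = filter_order, rb = rb, l_lt = l_lt,
         hampel_half_window = hampel_half_window,
         hampel_n_sigma = hampel_n_sigma,
         peaks = peaks, welch = welch, scaling = scaling,
         use_interp = use_interp, use_hampel = use_hampel,
         use_clip_repair = use_clip_repair),
    class = "pipeline_config"
  )
}

#' Split a record into consecutive analysis windows
#'
#' Non-overlapping windows from the start of the record; a trailing
#' remainder shorter than `window_s` is discarded.
#'
#' @param record A [ppg_record()].
#' @param window_s Window length in seconds.
#' @return A tibble with one row per window: `window` (1-based index),
#'   `start_idx`, `end_idx` (1-based, inclusive), `start_s`, `window_s`.
#' @examples
#' rec <- ppg_record(numeric(480 * 125) + 1, fs = 125)
#' nrow(segment_record(rec, 90)) # 5
#' @export
segment_record <- function(record, window_s) {
  stopifnot(inherits(record, "ppg_record"), window_s > 0)
  wlen <- round(window_s * record$fs)
  n_win <- length(record$samples) %/% wlen
  if (n_win < 1) {
    stop("record shorter than one analysis window", call. = FALSE)
  }
  k <- seq_len(n_win)
  tibble::tibble(
    window = k,
    start_idx = (k - 1) * wlen + 1,
    end_idx = k * wlen,
    start_s = (k - 1) * wlen / record$fs,
    window_s = window_s
  )
}

#' Estimate respiratory rate for every window of a record
#'
#' Runs the full pipeline per window: missing-value interpolation,
#' clipping repair, ESQI quality gate, cardiac band-pass, Hampel outlier
#' removal, peak enhancement, moving-average peak detection, false-peak
#' rejection, RR-interval formation, uniform resampling, Welch spectral
#' estimation, band-restricted rate extraction, amplitude scaling, and a
#' physiological clamp. A window that fails any stage yields a skipped
#' row with a reason; it never aborts the remaining windows.
#'
#' @param record A [ppg_record()].
#' @param cfg A [pipeline_config()].
#' @return A tibble of class `respyre_estimates`, one row per window:
#'   `window`, `start_s`, `window_s`, `respr` (breaths/min, `NA` when
#'   skipped), `esqi`, `hr_bpm`, `n_peaks`, `resp_band_range`, `scale`,
#'   `clamped`, `skipped`, `skip_reason`. The configuration and the
#'   record's reference rates travel along as attributes.
#' @export
estimate_record <- function(record, cfg = pipeline_config()) {
  stopifnot(inherits(record, "ppg_record"), inherits(cfg, "pipeline_config"))
  wins <- segment_record(record, cfg$window_s)
  rows <- purrr::pmap_dfr(
    wins,
    function(window, start_idx, end_idx, start_s, window_s) {
      .estimate_window(record$samples[start_idx:end_idx], record$fs,
                       window, start_s, window_s, cfg)
    }
  )
  attr(rows, "config") <- cfg
  attr(rows, "ref_resp") <- record$ref_resp
  attr(rows, "subject_id") <- record$subject_id
  class(rows) <- c("respyre_estimates", class(rows))
  rows
}

.skip_row <- function(window, start_s, window_s, reason, esqi_val = NA_real_) {
  tibble::tibble(
    window = window, start_s = start_s, window_s = window_s,
    respr = NA_real_, esqi = esqi_val, hr_bpm = NA_real_,
    n_peaks = NA_integer_, resp_band_range = NA_real_, scale = NA_real_,
    clamped = NA, skipped = TRUE, skip_reason = reason
  )
}

.estimate_window <- function(x, fs, window, start_s, window_s, cfg) {
  skip <- function(reason, esqi_val = NA_real_) {
    .skip_row(window, start_s, window_s, reason, esqi_val)
  }

  if (all(is.na(x))) return(skip("all-missing"))
  x <- if (cfg$use_interp) {
    interpolate_missing(x)
  } else {
    ifelse(is.na(x), 0, x)
  }
  if (max(x) - min(x) <= 0) return(skip("flat-window"))

  q <- esqi(x)
  if (!gate_window(q, cfg$use_esqi)) return(skip("esqi-undefined", q$esqi))

  # outlier spikes and saturation plateaus are features of the raw
  # signal; remove them before any filtering smears them out
  if (cfg$use_hampel) {
    x <- hampel_filter(x, cfg$hampel_half_window, cfg$hampel_n_sigma)$samples
  }
  if (cfg$use_clip_repair) {
    rep <- tryCatch(repair_clipping(x, cfg$peaks$clip_run_min),
                    error = function(e) NULL)
    if (!is.null(rep)) x <- rep$samples
  }

  resp_band <- bandpass(x, fs, cfg$band_low_hz, cfg$band_high_hz,
                        cfg$filter_order)
  resp_band_range <- max(resp_band) - min(resp_band)

  y <- bandpass(x, fs, cfg$cardiac_low_hz, cfg$cardiac_high_hz,
                cfg$filter_order)
  if (max(y) - min(y) <= 0) return(skip("flat-window", q$esqi))
  y <- enhance_peaks(y, cfg$rb, cfg$l_lt)

  peaks <- detect_peaks(y, fs, cfg$peaks)
  if (is.null(peaks)) return(skip("peak-detection", q$esqi))
  peaks <- reject_false_peaks(peaks, fs, cfg$peaks$false_peak_fraction)
  if (is.null(peaks)) return(skip("peak-detection", q$esqi))
  if (length(peaks) < 5) return(skip("too-few-beats", q$esqi))
  peaks <- fill_missed_beats(peaks, fs, cfg$peaks$missed_beat_factor)

  rr <- rr_series(peaks, fs)
  res <- resample_rr(rr, cfg$welch$resample_hz)
  if (length(res$series) < 8) return(skip("too-few-beats", q$esqi))
  spec <- welch_psd(res$series, res$fs, cfg$welch)
  raw <- respr_from_psd(spec, cfg$welch$band_low_hz, cfg$welch$band_high_hz)

  sc <- amplitude_scale(raw, resp_band_range, window_s, cfg$scaling)
  cl <- clamp_physiological(sc$respr, cfg$scaling$clamp_min,
                            cfg$scaling$clamp_max)

  tibble::tibble(
    window = window, start_s = start_s, window_s = window_s,
    respr = cl$respr, esqi = q$esqi, hr_bpm = heart_rate_bpm(rr),
    n_peaks = length(peaks), resp_band_range = resp_band_range,
    scale = sc$scale, clamped = cl$clamped,
    skipped = FALSE, skip_reason = NA_character_
  )
}

#' Mean absolute error
#' @param ref,est Equal-length numeric vectors (reference and estimate).
#' @return `mean(abs(ref - est))`.
#' @export
mae <- function(ref, est) {
  if (length(ref) != length(est) || length(ref) < 1) {
    stop("`ref` and `est` must be nonempty and of equal length",
         call. = FALSE)
  }
  mean(abs(ref - est))
}

#' Root mean square error
#' @param ref,est Equal-length numeric vectors (reference and estimate).
#' @return `sqrt(mean((ref - est)^2))`.
#' @export
rmse <- function(ref, est) {
  if (length(ref) != length(est) || length(ref) < 1) {
    stop("`ref` and `est` must be nonempty and of equal length",
         call. = FALSE)
  }
  sqrt(mean((ref - est)^2))
}

#' Pair windowed estimates with a reference rate series
#'
#' For each non-skipped window, the reference value is the mean of the
#' reference samples whose timestamps fall inside the window's span
#' (half-open `[start_s, start_s + window_s)`). Windows with no reference
#' coverage are excluded.
#'
#' @param estimates Tibble from [estimate_record()].
#' @param ref_resp Reference series: data frame with `time_s`,
#'   `resp_brpm`. Defaults to the series attached to `estimates`.
#' @return Tibble with `window`, `start_s`, `window_s`, `ref`, `est` and,
#'   when available, `resp_band_range`.
#' @export
pair_with_reference <- function(estimates, ref_resp = NULL) {
  if (is.null(ref_resp)) ref_resp <- attr(estimates, "ref_resp")
  if (is.null(ref_resp) || nrow(ref_resp) == 0) {
    stop("no reference respiratory rates available", call. = FALSE)
  }
  kept <- estimates[!estimates$skipped & !is.na(estimates$respr), ]
  if (nrow(kept) == 0) {
    stop("no usable windows: every window was skipped", call. = FALSE)
  }
  refs <- vapply(seq_len(nrow(kept)), function(i) {
    lo <- kept$start_s[i]
    hi <- lo + kept$window_s[i]
    v <- ref_resp$resp_brpm[ref_resp$time_s >= lo & ref_resp$time_s < hi]
    if (length(v) == 0) NA_real_ else mean(v)
  }, double(1))
  win_id <- if ("window" %in% names(kept)) kept$window else seq_len(nrow(kept))
  out <- tibble::tibble(
    window = win_id, start_s = kept$start_s, window_s = kept$window_s,
    ref = refs, est = kept$respr
  )
  if ("resp_band_range" %in% names(kept)) {
    out$resp_band_range <- kept$resp_band_range
  }
  out <- out[!is.na(out$ref), ]
  if (nrow(out) == 0) {
    stop("reference series does not overlap any analysis window",
         call. = FALSE)
  }
  out
}

#' Evaluate windowed estimates against their reference
#'
#' @param estimates Tibble from [estimate_record()].
#' @param ref_resp Optional reference series (see
#'   [pair_with_reference()]).
#' @return One-row tibble: `window_s`, `mae`, `rmse`, `n_windows`,
#'   `n_skipped`, `n_paired`.
#' @export
evaluate_estimates <- function(estimates, ref_resp = NULL) {
  pairs <- pair_with_reference(estimates, ref_resp)
  tibble::tibble(
    window_s = estimates$window_s[1],
    mae = mae(pairs$ref, pairs$est),
    rmse = rmse(pairs$ref, pairs$est),
    n_windows = nrow(estimates),
    n_skipped = sum(estimates$skipped),
    n_paired = nrow(pairs)
  )
}

#' Sweep candidate window sizes over a record
#'
#' @param record A [ppg_record()] with reference rates (or see
#'   `calib_brpm`).
#' @param cfg A [pipeline_config()]; its `window_s` is overridden by each
#'   candidate in turn.
#' @param candidate_windows Window sizes in seconds.
#' @param calib_brpm Optional single user-entered calibration rate used
#'   as the reference for every window (for device calibration by paced
#'   breathing) instead of `record$ref_resp`.
#' @return Tibble with one row per candidate (columns of
#'   [evaluate_estimates()]); candidates where no window could be
#'   estimated are dropped.
#' @export
sweep_windows <- function(record, cfg = pipeline_config(),
                          candidate_windows = c(10, 20, 30, 45, 60, 90, 120),
                          calib_brpm = NULL) {
  purrr::map_dfr(candidate_windows, function(w) {
    wcfg <- cfg
    wcfg$window_s <- w
    res <- tryCatch({
      est <- estimate_record(record, wcfg)
      ref <- if (!is.null(calib_brpm)) {
        tibble::tibble(
          time_s = seq(0, floor(ppg_duration(record)) - 1),
          resp_brpm = calib_brpm
        )
      } else {
        NULL
      }
      evaluate_estimates(est, ref)
    }, error = function(e) NULL)
    res
  })
}

#' Select the best analysis window size for a record
#'
#' Evaluates every candidate window size and returns the one with the
#' smallest MAE against the reference (ties go to the smaller, cheaper
#' window).
#'
#' @inheritParams sweep_windows
#' @return List with `window_s` (the winner) and `results` (the
#'   [sweep_windows()] tibble).
#' @export
select_best_window <- function(record, cfg = pipeline_config(),
                               candidate_windows = c(10, 20, 30, 45, 60,
                                                     90, 120),
                               calib_brpm = NULL) {
  res <- sweep_windows(record, cfg, candidate_windows, calib_brpm)
  if (nrow(res) == 0) {
    stop("no candidate window size produced any valid estimate",
         call. = FALSE)
  }
  res <- res[order(res$mae, res$window_s), ]
  list(window_s = res$window_s[1], results = res)
}
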
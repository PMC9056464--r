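#' Amplitude-variation scaling configuration
#'
#' The estimate can be rescaled by how strongly respiration modulates the
#' PPG amplitude: the correction is multiplicative,
#' `scale = 1 + gain * (range / ref_range - 1) / window_s`, where `range`
#' is the amplitude range of the respiratory-band (0.1-0.4 Hz) waveform
#' in the window. With the default `gain = 0` the stage is the identity;
#' `gain` and `ref_range` are meant to be set by [calibrate_scaling()]
#' against reference data.
#'
#' @param enabled Logical; apply the scaling stage at all.
#' @param ref_range Reference amplitude range (calibration constant,
#'   default 1).
#' @param gain Sensitivity of the correction (default 0 = identity).
#' @param clamp_min,clamp_max Physiological bounds in breaths/min
#'   (defaults 6 and 45).
#' @return A `scaling_config` list.
#' @export
scaling_config <- function(enabled = TRUE, ref_range = 1, gain = 0,
                           clamp_min = 6, clamp_max = 45) {
  stopifnot(ref_range > 0, gain >= 0, clamp_min < clamp_max)
  structure(
    list(enabled = enabled, ref_range = ref_range, gain = gain,
         clamp_min = clamp_min, clamp_max = clamp_max),
    class = "scaling_config"
  )
}

#' Scale a raw rate estimate by respiratory amplitude variation
#'
#' @param respr_raw Raw respiratory-rate estimate, breaths/min.
#' @param resp_band_range Amplitude range (max - min) of the
#'   respiratory-band waveform in the window.
#' @param window_s Window length in seconds.
#' @param cfg A [scaling_config()].
#' @return List with `respr` (scaled value) and `scale` (the factor
#'   applied; 1 when the stage is disabled or `gain = 0`).
#' @examples
#' amplitude_scale(15, 2, 10, scaling_config(gain = 1))$respr # 16.5
#' @export
amplitude_scale <- function(respr_raw, resp_band_range, window_s,
                            cfg = scaling_config()) {
  stopifnot(is.finite(respr_raw), resp_band_range >= 0, window_s > 0)
  if (!cfg$enabled || cfg$gain == 0) {
    return(list(respr = respr_raw, scale = 1))
  }
  scale <- 1 + cfg$gain * (resp_band_range / cfg$ref_range - 1) / window_s
  list(respr = respr_raw * scale, scale = scale)
}

#' Clamp an estimate to a physiological range
#'
#' @param respr Respiratory rate in breaths/min.
#' @param clamp_min,clamp_max Bounds in breaths/min.
#' @return List with `respr` (clamped value) and `clamped` (logical flag,
#'   `TRUE` when limiting occurred).
#' @export
clamp_physiological <- function(respr, clamp_min = 6, clamp_max = 45) {
  stopifnot(is.finite(respr), clamp_min < clamp_max)
  out <- min(max(respr, clamp_min), clamp_max)
  list(respr = out, clamped = out != respr)
}

#' Calibrate the amplitude-scaling parameters against reference data
#'
#' Grid search over `(gain, ref_range)` minimising the MAE of the scaled
#' estimates against the reference rates, pooled over the supplied
#' records. The search grid is fixed, so the result is deterministic.
#'
#' @param records List of [ppg_record()]s with nonempty `ref_resp`.
#' @param cfg A [pipeline_config()] used to produce the raw estimates.
#' @param gain_grid,ref_range_grid Search grids.
#' @return A [scaling_config()] with the winning `gain` and `ref_range`
#'   (ties resolved toward smaller gain, then smaller ref_range).
#' @export
calibrate_scaling <- function(records, cfg = pipeline_config(),
                              gain_grid = seq(0, 5, by = 0.5),
                              ref_range_grid = c(0.25, 0.5, 1, 2, 4)) {
  if (length(records) == 0) {
    stop("no records supplied for calibration", call. = FALSE)
  }
  if (!all(vapply(records, function(r) nrow(r$ref_resp) > 0, logical(1)))) {
    stop("every calibration record needs reference rates", call. = FALSE)
  }
  raw_cfg <- cfg
  raw_cfg$scaling <- scaling_config(gain = 0,
                                    clamp_min = cfg$scaling$clamp_min,
                                    clamp_max = cfg$scaling$clamp_max)
  runs <- lapply(records, function(rec) {
    est <- estimate_record(rec, raw_cfg)
    pr <- pair_with_reference(est, rec$ref_resp)
    ok <- !est$skipped
    list(raw = est$respr[ok], range = est$resp_band_range[ok],
         paired = pr)
  })

  best <- NULL
  best_mae <- Inf
  for (g in gain_grid) {
    for (rr in ref_range_grid) {
      errs <- unlist(lapply(runs, function(run) {
        pr <- run$paired
        scale <- 1 + g * (pr$resp_band_range / rr - 1) / pr$window_s
        est <- pmin(pmax(pr$est * scale, cfg$scaling$clamp_min),
                    cfg$scaling$clamp_max)
        abs(pr$ref - est)
      }))
      m <- mean(errs)
      if (m < best_mae - 1e-12) {
        best_mae <- m
        best <- c(gain = g, ref_range = rr)
      }
    }
  }
  scaling_config(enabled = TRUE, ref_range = best[["ref_range"]],
                 gain = best[["gain"]],
                 clamp_min = cfg$scaling$clamp_min,
                 clamp_max = cfg$scaling$clamp_max)
}
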
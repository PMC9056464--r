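#' Peak-detection configuration
#'
#' @param ma_window_s Moving-average span in seconds (default 0.75).
#' @param raise_percentages Candidate elevations of the moving-average
#'   threshold, in percent of the signal's amplitude range (default
#'   5,10,...,40). The sweep picks the elevation whose implied heart rate
#'   is plausible and whose RR intervals are most regular.
#' @param bpm_min,bpm_max Plausible heart-rate band for the sweep
#'   (defaults 40 and 180 bpm).
#' @param clip_run_min Minimum consecutive samples at the signal ceiling
#'   to declare saturation clipping (default 3).
#' @param false_peak_fraction An interval shorter than this fraction of
#'   the mean RR interval marks a false peak (default 0.30).
#' @param missed_beat_factor An interval longer than this multiple of the
#'   median interval is treated as spanning missed beats and subdivided
#'   by [fill_missed_beats()] (default 1.7; `Inf` disables).
#' @return A `peak_detect_config` list.
#' @export
peak_detect_config <- function(ma_window_s = 0.75,
                               raise_percentages = seq(5, 40, by = 5),
                               bpm_min = 40, bpm_max = 180,
                               clip_run_min = 3,
                               false_peak_fraction = 0.30,
                               missed_beat_factor = 1.7) {
  stopifnot(ma_window_s > 0, length(raise_percentages) >= 1,
            bpm_min > 0, bpm_max > bpm_min, clip_run_min >= 1,
            false_peak_fraction > 0, false_peak_fraction < 1,
            missed_beat_factor > 1)
  structure(
    list(ma_window_s = ma_window_s, raise_percentages = raise_percentages,
         bpm_min = bpm_min, bpm_max = bpm_max, clip_run_min = clip_run_min,
         false_peak_fraction = false_peak_fraction,
         missed_beat_factor = missed_beat_factor),
    class = "peak_detect_config"
  )
}

#' Repair saturation-clipped stretches by cubic-spline interpolation
#'
#' Sensor saturation flattens pulse apices at the signal ceiling. Maximal
#' runs of at least `clip_run_min` consecutive samples at the global
#' maximum (within 1e-9 relative) are treated as clipped and replaced by
#' a cubic spline fitted through the 3 nearest non-clipped samples on
#' each side, restoring a plausible apex above the clip level. A run
#' touching one end of the signal has no anchors on that side and is left
#' unrepaired; a run covering the whole signal is an error.
#'
#' @param samples Numeric vector without missing values.
#' @param clip_run_min Minimum run length to declare clipping (default 3).
#' @return List with `samples` (repaired) and `clipped_spans` (two-column
#'   matrix of 1-based inclusive start/end indices; zero rows when no
#'   clipping was found).
#' @export
repair_clipping <- function(samples, clip_run_min = 3) {
  if (anyNA(samples)) stop("`samples` must not contain missing values",
                           call. = FALSE)
  x <- as.double(samples)
  n <- length(x)
  mx <- max(x)
  tol <- 1e-9 * max(abs(mx), 1)
  at_max <- x >= mx - tol

  spans <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  r <- rle(at_max)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in which(r$values & r$lengths >= clip_run_min)) {
    s <- starts[j]; e <- ends[j]
    if (s == 1 && e == n) {
      stop("clipped run spans the whole signal; nothing to anchor",
           call. = FALSE)
    }
    left <- if (s > 1) max(1, s - 3):(s - 1) else integer(0)
    right <- if (e < n) (e + 1):min(n, e + 3) else integer(0)
    anchors <- c(left, right)
    if (length(left) == 0 || length(right) == 0) {
      # a run touching one signal end has no anchors on that side;
      # extrapolating a spline there is unreliable, so leave it as is
      next
    }
    sf <- stats::splinefun(anchors, x[anchors], method = "fmm")
    # a cubic across a wide gap amplifies anchor noise; bound the restored
    # apex by one shoulder-rise above the clip level and floor it at the
    # lowest anchor so the repair can never be wilder than the data
    lo <- min(x[anchors])
    x[s:e] <- pmin(pmax(sf(s:e), lo), mx + (mx - lo))
    spans <- rbind(spans, c(s, e))
  }
  list(samples = x, clipped_spans = spans)
}

#' Detect systolic peaks with an elevated moving-average threshold
#'
#' A moving average of span `ma_window_s` is raised by a percentage of
#' the signal's amplitude range to form a threshold curve; maximal runs
#' where the signal exceeds the threshold are regions of interest (ROI),
#' and each ROI contributes one peak at its maximum (earliest index on
#' ties). The elevation percentage is swept over
#' `cfg$raise_percentages`; among elevations whose implied mean heart
#' rate falls in `[bpm_min, bpm_max]`, the one with the smallest RR
#' standard deviation wins (lowest percentage on ties).
#'
#' @param samples Peak-enhanced signal without missing values.
#' @param fs Sampling frequency in Hz.
#' @param cfg A [peak_detect_config()].
#' @return Strictly increasing 1-based peak indices, or `NULL` when no
#'   elevation yields at least 2 plausible peaks (detection failure; the
#'   caller skips the window).
#' @export
detect_peaks <- function(samples, fs, cfg = peak_detect_config()) {
  if (anyNA(samples)) stop("`samples` must not contain missing values",
                           call. = FALSE)
  n <- length(samples)
  span <- max(1L, round(cfg$ma_window_s * fs))
  if (n < 2 * span) {
    stop("window shorter than twice the moving-average span", call. = FALSE)
  }
  rng <- max(samples) - min(samples)
  if (rng <= 0) return(NULL)

  ma <- .moving_average(samples, span)

  best <- NULL
  best_sd <- Inf
  for (p in cfg$raise_percentages) {
    thr <- ma + p / 100 * rng
    peaks <- .roi_peaks(samples, thr)
    if (length(peaks) < 2) next
    rr_s <- diff(peaks) / fs
    bpm <- 60 / mean(rr_s)
    if (bpm < cfg$bpm_min || bpm > cfg$bpm_max) next
    s <- if (length(rr_s) < 2) Inf else stats::sd(rr_s)
    if (is.null(best) || s < best_sd) {
      best_sd <- s
      best <- peaks
    }
  }
  best
}

# centred moving average; edges use the mean of the available samples
.moving_average <- function(x, span) {
  hw <- span %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(1, seq_len(n) - hw)
  hi <- pmin(n, seq_len(n) + hw)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# one peak per threshold-exceeding run, at the run's argmax (earliest tie)
.roi_peaks <- function(x, thr) {
  above <- x > thr
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  vapply(idx, function(j) {
    seg <- starts[j]:ends[j]
    seg[which.max(x[seg])]
  }, integer(1))
}

#' Reject false peaks by the 30% mean-interval rule
#'
#' An inter-peak interval shorter than `fraction` times the mean interval
#' marks a false peak; the later peak of the offending pair is dropped,
#' the intervals are recomputed, and the rule is re-applied until every
#' interval passes. Keeping the earlier peak preserves the established
#' rhythm.
#'
#' @param peak_indices Strictly increasing peak indices (at least 2).
#' @param fs Sampling frequency in Hz (intervals are compared as ratios,
#'   so `fs` only validates the input scale).
#' @param fraction Rejection threshold as a fraction of the mean RR
#'   interval (default 0.30).
#' @return Cleaned strictly increasing peak indices, or `NULL` when fewer
#'   than 2 peaks remain.
#' @export
reject_false_peaks <- function(peak_indices, fs, fraction = 0.30) {
  p <- as.double(peak_indices)
  if (length(p) < 2) stop("need at least 2 peaks", call. = FALSE)
  if (any(diff(p) <= 0)) {
    stop("`peak_indices` must be strictly increasing", call. = FALSE)
  }
  repeat {
    if (length(p) < 2) return(NULL)
    iv <- diff(p)
    bad <- which(iv < fraction * mean(iv))
    if (length(bad) == 0) return(p)
    p <- p[-(bad[1] + 1)] # drop the later peak of the first offending pair
  }
}

#' Subdivide intervals that span missed beats
#'
#' A signal dropout can swallow one or more pulses, leaving an inter-peak
#' interval of roughly an integer multiple of the beat period. Such an
#' interval would dominate the RR power spectrum far beyond the
#' respiratory modulation it hides. Any interval longer than
#' `gap_factor` times the median interval is split into
#' `round(interval / median)` equal sub-intervals by inserting synthetic
#' peak positions, restoring a near-regular beat grid across the gap.
#'
#' @param peak_indices Strictly increasing peak indices (at least 2).
#' @param fs Sampling frequency in Hz (validates the input scale only;
#'   the rule compares interval ratios).
#' @param gap_factor Threshold as a multiple of the median interval
#'   (default 1.7, below twice the period so a single missed beat is
#'   caught; `Inf` disables the correction).
#' @return Strictly increasing (possibly fractional) peak positions.
#' @export
fill_missed_beats <- function(peak_indices, fs, gap_factor = 1.7) {
  p <- as.double(peak_indices)
  if (length(p) < 2) stop("need at least 2 peaks", call. = FALSE)
  if (any(diff(p) <= 0)) {
    stop("`peak_indices` must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(gap_factor)) return(p)
  iv <- diff(p)
  med <- stats::median(iv)
  out <- p[1]
  for (k in seq_along(iv)) {
    if (iv[k] > gap_factor * med) {
      m <- max(2L, round(iv[k] / med))
      out <- c(out, p[k] + iv[k] / m * seq_len(m))
    } else {
      out <- c(out, p[k + 1])
    }
  }
  out
}
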
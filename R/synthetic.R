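#' Synthetic PPG generator configuration
#'
#' Describes a simulated finger-PPG recording whose beat-to-beat intervals
#' are frequency-modulated at the respiratory frequency (respiratory sinus
#' arrhythmia) and whose pulse amplitudes are amplitude-modulated at the
#' same frequency (respiratory-induced amplitude variation). Optional
#' artefacts emulate the failure modes the pipeline has to survive:
#' additive sensor noise, slow baseline wander, isolated spike outliers
#' from probe movement, NaN dropout runs from signal loss, and amplitude
#' clipping from sensor saturation.
#'
#' @param duration_s Record duration in seconds.
#' @param fs Sampling frequency in Hz (default 125, the usual monitor
#'   export rate).
#' @param hr_bpm Mean heart rate in beats per minute.
#' @param resp_hz Respiratory frequency in Hz; the physiological band is
#'   0.1-0.4 Hz (6-24 breaths/min). Values outside it are allowed for
#'   negative tests.
#' @param fm_depth Fractional modulation of the beat interval by
#'   respiration (RSA depth), in `[0, 0.5]`.
#' @param am_depth Fractional modulation of pulse amplitude by
#'   respiration (RIAV depth), in `[0, 0.5]`.
#' @param noise_sd Standard deviation of additive white noise, in units of
#'   the unit-amplitude pulse template.
#' @param wander_amp,wander_hz Amplitude and frequency of a sinusoidal
#'   baseline wander.
#' @param spike_rate Expected isolated spike outliers per minute.
#' @param dropout_rate Expected NaN dropout runs per minute.
#' @param dropout_len_s Length of each dropout run, seconds.
#' @param clip_level Absolute saturation threshold, or `NULL` for no
#'   clipping.
#' @param clip_quantile Alternative to `clip_level`: clip at this quantile
#'   of the pre-artefact signal (e.g. 0.95 clips the top 5% of samples).
#' @param seed Integer RNG seed; the generated record is a pure function
#'   of the configuration.
#' @return A `synth_config` list.
#' @export
synth_config <- function(duration_s = 480, fs = 125, hr_bpm = 70,
                         resp_hz = 0.25, fm_depth = 0.05, am_depth = 0.2,
                         noise_sd = 0.02, wander_amp = 0.1, wander_hz = 0.05,
                         spike_rate = 0, dropout_rate = 0, dropout_len_s = 1,
                         clip_level = NULL, clip_quantile = NULL, seed = 1L) {
  stopifnot(duration_s > 0, fs > 0, hr_bpm > 0, resp_hz > 0,
            fm_depth >= 0, fm_depth <= 0.5, am_depth >= 0, am_depth <= 0.5,
            noise_sd >= 0, spike_rate >= 0, dropout_rate >= 0)
  structure(
    list(
      duration_s = duration_s, fs = fs, hr_bpm = hr_bpm, resp_hz = resp_hz,
      fm_depth = fm_depth, am_depth = am_depth, noise_sd = noise_sd,
      wander_amp = wander_amp, wander_hz = wander_hz,
      spike_rate = spike_rate, dropout_rate = dropout_rate,
      dropout_len_s = dropout_len_s, clip_level = clip_level,
      clip_quantile = clip_quantile, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# skewed positive pulse: fast rise to the systolic peak, slower decay.
# gamma-like shape (tau/tau_r)^2 exp(2 (1 - tau/tau_r)), peak at tau_r.
.pulse_template <- function(fs, width_s = 0.35, rise_s = 0.12) {
  tau <- seq(0, width_s, by = 1 / fs)
  u <- tau / rise_s
  u^2 * exp(2 * (1 - u))
}

#' Generate a synthetic PPG record with known ground truth
#'
#' Beat times are produced iteratively: the k-th interval is
#' `(60 / hr_bpm) * (1 + fm_depth * sin(2 pi resp_hz t_k))`, so the
#' instantaneous heart period oscillates at the respiratory frequency.
#' Each beat renders a fixed asymmetric pulse template (width ~0.35 s)
#' scaled by `1 + am_depth * sin(2 pi resp_hz t_k)`. Baseline wander and
#' white noise are added, then spikes, NaN dropouts and clipping in that
#' order. The whole record is reproducible from the seed.
#'
#' @param config A [synth_config()].
#' @return A list with elements `record` (a [ppg_record()] whose
#'   `ref_resp` holds the constant true rate at 1 Hz) and `truth` (a list:
#'   `resp_hz`, `resp_brpm`, `hr_bpm`, `beat_times`, `pulse_peak_offset_s`,
#'   `spike_indices`, `dropout_spans`, `clipped_spans`, `clip_level`; all
#'   indices 1-based, spans as two-column start/end matrices, inclusive).
#' @examples
#' sim <- synth_ppg(synth_config(duration_s = 30, resp_hz = 0.25, seed = 7))
#' sim$truth$resp_brpm # 15
#' @export
synth_ppg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  if (cfg$duration_s < 2 * 60 / cfg$hr_bpm) {
    stop("duration too short to contain at least 2 beats", call. = FALSE)
  }
  withr::with_seed(cfg$seed, {
    # beat train with respiratory frequency modulation (RSA)
    beat_times <- 0
    repeat {
      t_k <- beat_times[length(beat_times)]
      iv <- (60 / cfg$hr_bpm) *
        (1 + cfg$fm_depth * sin(2 * pi * cfg$resp_hz * t_k))
      t_next <- t_k + iv
      if (t_next > cfg$duration_s) break
      beat_times <- c(beat_times, t_next)
    }

    n <- round(cfg$duration_s * cfg$fs)
    tgrid <- (seq_len(n) - 1) / cfg$fs
    x <- numeric(n)
    template <- .pulse_template(cfg$fs)
    lt <- length(template)
    for (t_k in beat_times) {
      i0 <- round(t_k * cfg$fs) + 1
      if (i0 > n) next
      idx <- i0:min(i0 + lt - 1, n)
      amp <- 1 + cfg$am_depth * sin(2 * pi * cfg$resp_hz * t_k)
      x[idx] <- x[idx] + amp * template[seq_along(idx)]
    }

    x <- x + cfg$wander_amp * sin(2 * pi * cfg$wander_hz * tgrid)
    if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, sd = cfg$noise_sd)

    # isolated spikes: single-sample excursions of 5-10x the signal range
    spike_indices <- integer(0)
    n_spikes <- stats::rpois(1, cfg$spike_rate * cfg$duration_s / 60)
    if (n_spikes > 0) {
      spike_indices <- sort(sample.int(n, n_spikes))
      rng <- diff(range(x))
      mag <- stats::runif(n_spikes, 5, 10) * rng *
        sample(c(-1, 1), n_spikes, replace = TRUE)
      x[spike_indices] <- x[spike_indices] + mag
    }

    # NaN dropout runs
    dropout_spans <- matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("start", "end")))
    n_drop <- stats::rpois(1, cfg$dropout_rate * cfg$duration_s / 60)
    if (n_drop > 0) {
      len <- max(1, round(cfg$dropout_len_s * cfg$fs))
      starts <- sort(sample.int(max(1, n - len), n_drop))
      for (s in starts) {
        e <- min(s + len - 1, n)
        x[s:e] <- NA_real_
        dropout_spans <- rbind(dropout_spans, c(s, e))
      }
    }

    # saturation clipping
    clip_level <- cfg$clip_level
    if (is.null(clip_level) && !is.null(cfg$clip_quantile)) {
      clip_level <- stats::quantile(x, cfg$clip_quantile, na.rm = TRUE,
                                    names = FALSE)
    }
    clipped_spans <- matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("start", "end")))
    if (!is.null(clip_level)) {
      over <- which(!is.na(x) & x > clip_level)
      x[over] <- clip_level
      if (length(over)) {
        brk <- c(0, which(diff(over) > 1), length(over))
        clipped_spans <- cbind(
          start = over[brk[-length(brk)] + 1],
          end = over[brk[-1]]
        )
      }
    }

    ref <- tibble::tibble(
      time_s = seq(0, floor(cfg$duration_s) - 1),
      resp_brpm = cfg$resp_hz * 60
    )
    list(
      record = ppg_record(x, fs = cfg$fs, ref_resp = ref,
                          subject_id = sprintf("synth-seed%d", cfg$seed)),
      truth = list(
        resp_hz = cfg$resp_hz, resp_brpm = cfg$resp_hz * 60,
        hr_bpm = cfg$hr_bpm, beat_times = beat_times,
        pulse_peak_offset_s = 0.12,
        spike_indices = spike_indices, dropout_spans = dropout_spans,
        clipped_spans = clipped_spans, clip_level = clip_level
      )
    )
  })
}

#' Write a fixed battery of synthetic fixture records
#'
#' Produces a reproducible suite of records spanning respiratory rates
#' 8-23 breaths/min, in clean and artefact-laden variants, each with a
#' key-value truth sidecar file. Intended for tests and demos that must
#' run without downloading data.
#'
#' @param out_dir Output directory (created if needed).
#' @param duration_s Duration of each record, seconds.
#' @param seed Base RNG seed; record seeds are derived from it.
#' @return Invisibly, a tibble listing the files and their ground truth.
#' @export
make_fixture_suite <- function(out_dir, duration_s = 120, seed = 20L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop("directory is not writable: ", out_dir, call. = FALSE)
  }
  rates <- c(8, 10, 12, 15, 18, 20, 23)
  specs <- c(
    lapply(seq_along(rates), function(i) {
      list(name = sprintf("clean_r%02d", rates[i]),
           cfg = synth_config(duration_s = duration_s, resp_hz = rates[i] / 60,
                              seed = seed + i))
    }),
    lapply(seq_along(rates[c(2, 4, 6)]), function(i) {
      r <- rates[c(2, 4, 6)][i]
      list(name = sprintf("artefact_r%02d", r),
           cfg = synth_config(duration_s = duration_s, resp_hz = r / 60,
                              spike_rate = 2, dropout_rate = 1,
                              clip_quantile = 0.95, seed = seed + 100 + i))
    })
  )
  rows <- purrr::map_dfr(specs, function(sp) {
    sim <- synth_ppg(sp$cfg)
    sig_path <- file.path(out_dir, paste0(sp$name, ".csv"))
    truth_path <- file.path(out_dir, paste0(sp$name, "_truth.txt"))
    tm <- (seq_along(sim$record$samples) - 1) / sim$record$fs
    utils::write.csv(
      data.frame(time = sprintf("%.6f", tm),
                 ppg = sprintf("%.6f", sim$record$samples)),
      sig_path, row.names = FALSE, quote = FALSE, na = ""
    )
    writeLines(c(
      sprintf("resp_brpm=%g", sim$truth$resp_brpm),
      sprintf("resp_hz=%g", sim$truth$resp_hz),
      sprintf("hr_bpm=%g", sim$truth$hr_bpm),
      sprintf("fs=%g", sim$record$fs),
      sprintf("seed=%d", sp$cfg$seed),
      sprintf("n_spikes=%d", length(sim$truth$spike_indices)),
      sprintf("n_dropouts=%d", nrow(sim$truth$dropout_spans))
    ), truth_path)
    tibble::tibble(
      name = sp$name, signal_file = sig_path, truth_file = truth_path,
      resp_brpm = sim$truth$resp_brpm, hr_bpm = sim$truth$hr_bpm,
      seed = sp$cfg$seed
    )
  })
  invisible(rows)
}
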
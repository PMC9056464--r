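---
title: "Estimating respiratory rate from the PPG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating respiratory rate from the PPG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(respyre)
```

## The physiological signal model

Breathing modulates a finger photoplethysmogram (PPG) through two
channels. **Respiratory sinus arrhythmia (RSA)** modulates the
beat-to-beat (RR) intervals: the heart speeds up slightly on
inhalation and slows on exhalation, so the RR-interval sequence carries
a component at the respiratory frequency. **Respiratory-induced
amplitude variation (RIAV)** modulates pulse height: inhalation lowers
left-ventricular stroke volume and with it the pulse amplitude.

`respyre` estimates the respiratory rate per analysis window from the
RSA channel: detect systolic peaks, form the RR-interval series, and
take the frequency of the maximum of its Welch power spectral density
restricted to the physiological band 0.1--0.4 Hz (6--24 breaths/min),
times 60. The estimate is therefore confined to that band by
construction. The RIAV channel enters only through the optional
post-processing scaling stage (below).

The method assumes the rate is quasi-stationary within a window, that
the respiratory frequency lies in 0.1--0.4 Hz, and that enough beats
are detected to resolve it (a 90 s window at 4 Hz resampling gives a
frequency resolution of about 0.011 Hz, i.e. 0.67 breaths/min).

## Pipeline and the order of stages

Per window: missing-sample interpolation → entropy quality gate →
Hampel outlier removal → clipping repair → respiratory-band (0.1--0.4
Hz) and cardiac-band (0.5--3.5 Hz) zero-phase Butterworth filtering →
peak enhancement → moving-average peak detection → false-peak
rejection (30% rule) → missed-beat correction → RR series → cubic
resampling to 4 Hz → Welch PSD → band-restricted maximum → amplitude
scaling → physiological clamp. A window failing any stage yields a
skipped row with a reason; it never aborts the rest of the record.

Two ordering choices deserve comment.

* **Peak detection runs on the cardiac band, not the respiratory
  band.** A 0.1--0.4 Hz waveform contains no cardiac peaks; the
  respiratory-band branch is kept only as the amplitude-range input to
  the scaling stage. Both bands are configurable
  (`pipeline_config()`).
* **Hampel and clipping repair run on the raw interpolated signal,
  before any filtering.** A movement spike is a single-sample excursion
  and a saturation plateau is a flat run at the signal ceiling — both
  are features of the *raw* waveform. Band-pass filtering first would
  smear a spike into seconds of ringing that a 7-point Hampel window
  cannot reject, and would destroy the flat runs the clipping detector
  keys on.

## Stage details and numerical choices

**Interpolation.** Isolated missing samples become the mean of their
neighbours; runs are filled linearly between the bounding values; runs
touching an end take the nearest observed value. Implemented via
`zoo::na.approx(rule = 2)`, which has exactly these semantics.

**Entropy signal-quality index (ESQI).** `E = -sum(x^2 ln x^2)` over
the raw-scale window. Any sample with `|x| <= 1e-12` makes the index
undefined (the `0 * ln 0` pathology, with an underflow guard) and the
window is skipped when gating is enabled. The index is evaluated after
interpolation but before enhancement, and no normalisation is applied,
so it is deliberately scale-sensitive.

**Hampel filter.** Window of `half_window = 3` neighbours per side;
spread `sigma = 1.4826 * MAD` (the consistent estimator for Gaussian
data); replacement threshold `3 sigma`. The signal is end-padded with
`half_window` copies of its mean so the final samples sit in full
windows; start-edge windows are simply truncated. Replacement is
non-recursive.

**Clipping repair.** Maximal runs of `>= 3` samples at the global
maximum (within 1e-9 relative) are treated as saturated and replaced
by a cubic spline through the 3 nearest non-clipped samples per side.
An unbounded cubic across a wide plateau amplifies anchor noise, so
repaired values are clamped to
`[min(anchors), clip_level + (clip_level - min(anchors))]` — at most
one shoulder-rise above the ceiling. Runs touching a signal end have
no anchors on that side and are left unrepaired.

**Peak enhancement.** Linear rescaling onto `[l_lt, l_lt + rb]`
(defaults 0 and 1024). Order-preserving, so peak positions are
untouched; it only fixes the dynamic range seen by the threshold.

**Peak detection.** A centred moving average (span 0.75 s) is elevated
by p% of the window's amplitude range; maximal runs above the
threshold are regions of interest, each contributing one peak at its
argmax (earliest index on ties). p is swept over 5, 10, ..., 40; among
elevations whose implied mean rate is a plausible heart rate (40--180
bpm) the one with the most regular RR intervals (smallest SD) wins,
ties to the lowest elevation. No elevation yielding two plausible
peaks is a detection failure and skips the window.

**False peaks and missed beats.** An interval below 30% of the mean
interval marks a false peak; the later peak of the first offending
pair is dropped and the rule re-applied until clean (keeping the
earlier peak preserves the established rhythm). Conversely, an
interval above 1.7 times the *median* interval is taken to span missed
beats (a dropout that swallowed pulses) and is subdivided into
`round(interval / median)` equal parts; 1.7 sits safely below twice
the period, so a single missed beat is caught, while normal RSA
variability (a few percent) never triggers it. Without this
correction a single one-second dropout injects a double-length
interval whose spectral leakage can bury the RSA line.

**Spectral estimation.** The RR values sit at their cumulative-time
positions and are cubic-spline resampled onto a uniform 4 Hz grid
(comfortably above twice the 0.4 Hz band edge), then mean-centred.
Welch: segments of half the series length with 50% overlap (three
segments), periodic Hann taper, per-segment mean removal, FFT
zero-padded to the full series length with a floor of 256 bins,
one-sided density scaling normalised by the taper power, mean
averaging. Ties at the band maximum resolve to the lowest frequency
(the physiologically slower rate).

**Post-processing.** The raw estimate can be scaled multiplicatively
by how far the respiratory-band amplitude range deviates from a
reference range, damped by the window length:
`scale = 1 + gain * (range / ref_range - 1) / window_s`. Only the
inputs of this correction are physiologically dictated; its functional
form here is a declared parametric stand-in with `gain = 0` (identity)
until `calibrate_scaling()` sets it by deterministic grid search
against reference data. Finally the estimate is clamped to 6--45
breaths/min (the ceiling sits above the paediatric upper normal of 40
as a safety margin) and flagged if limiting occurred.

## The synthetic generator

`synth_ppg()` renders what the estimator exploits and what breaks it:
beat times generated iteratively with the interval modulated by
`fm_depth` (RSA) at the respiratory frequency, each beat a skewed
positive pulse — `(tau/0.12)^2 exp(2(1 - tau/0.12))`, fast rise to a
peak 0.12 s after onset, slow decay, 0.35 s support — scaled by
`1 + am_depth sin(2 pi f t)` (RIAV); plus a wander sinusoid, white
noise, single-sample spikes of 5--10 times the signal range, NaN
dropout runs, and optional hard clipping at a level or quantile.
Defaults (`noise_sd = 0.02`, `wander_amp = 0.1` at 0.05 Hz, in units
of the unit pulse) represent a moderately noisy but usable recording.

What it does **not** emulate: the dicrotic notch and two-wave pulse
morphology, baseline-wander modulation as a third respiratory channel,
coloured/motion noise, non-stationary breathing, and — notably — a DC
offset: the inter-pulse baseline sits near zero. Passing tests
therefore show the pipeline recovers rates under controlled RSA/RIAV
with these artefact models, not that it matches any clinical
benchmark; evaluation on real monitor exports (the paired
signals/numerics CSV layout, `read_bidmc_pair()`) is supported but
requires the user to obtain the data.

Two ablation findings follow directly from the generator's structure
and are worth knowing. Zero-substitution of missing samples is nearly
as good as interpolation *on these records* because the baseline is
already near zero — on real data with a DC offset, zeros would be far
more destructive. And clipping repair does not reduce the rate error
here because zero-phase cardiac-band filtering maps a flat-topped
pulse to a stable rounded apex: peak *timing*, the only thing the
RR-spectral estimator uses, survives clipping; the repair stage earns
its keep by restoring the *amplitude* channel that the scaling stage
consumes.

## Study sizes used by the test suite

The bundled acceptance study uses 24 records of 480 s at 125 Hz
(respiratory rates 8--22 breaths/min crossed with heart rates 55--90
bpm, `fm_depth = 0.05`, `am_depth = 0.2`), analysed in 90 s windows,
in clean and artefact-laden variants (2 spikes/min, one 1 s
dropout/min, clipping of the top 5% of samples); ablation comparisons
use a 9-record subgrid at 270 s. Oracle-equivalence checks run the
Hampel and false-peak stages against literal brute-force
re-implementations on 100 random inputs each, and the Welch estimator
against a directly computed Hann periodogram.

## A worked example

```{r example}
sim <- synth_ppg(synth_config(duration_s = 480, resp_hz = 15 / 60,
                              hr_bpm = 70, seed = 42))
est <- estimate_record(sim$record, pipeline_config(window_s = 90))
est[, c("window", "start_s", "respr", "esqi", "hr_bpm", "skipped")]
glance(est)
```

```{r plots, fig.height = 3}
autoplot(est)
```

## Known limitations

* The estimate is band-limited to 6--24 breaths/min; true rates
  outside the band are folded to the nearest band edge.
* Windows shorter than ~30 s resolve the band poorly (too few beats,
  too little frequency resolution); the error of very short windows is
  dominated by this, which is why long windows win on stationary
  signals.
* The amplitude-scaling stage is an identity until calibrated; its
  functional form is this package's own parameterisation of a
  dependency stated only qualitatively in the source method.
* `fill_missed_beats()` assumes a dropout at most doubles a few
  intervals; pathological rhythms (bigeminy, atrial fibrillation)
  violate the near-regular-grid assumption throughout.
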
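---
title: "Methods: coupling phasic pupil dilations to cortical EEG state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling phasic pupil dilations to cortical EEG state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilstate)
```

## The analysis

Pupil size under constant luminance indexes central arousal. Brief,
seconds-scale ("phasic") dilations mark transient arousal events; they arise
spontaneously and can be evoked by stimulating noradrenergic nuclei. The
question this pipeline operationalizes is how cortical state — the
distribution of EEG power across frequency bands — reorganizes around such
dilations, and whether spontaneous and stimulation-evoked dilations carry
distinguishable cortical signatures.

The pipeline has five analysis stages plus a synthetic-data generator:

1. **Pupil preprocessing and dilation detection.** The 10 Hz pupil trace is
   blink-interpolated, low-passed, z-scored, spline-upsampled to 100 Hz and
   high-passed at 0.1 Hz. A 10 s window slides in 0.01 s steps; a window
   qualifies when its first 2 s stay continuously below a z threshold
   (default 0.5 SD), the first supra-threshold local maximum is the dilation
   peak, and the event is kept only if the trace returns below threshold
   within 6 s. Each event carries a baseline (mean over [-6, -4) s before
   the peak) and an amplitude (mean over [-2.5, 2.5) s minus baseline).
2. **EEG band power on the pupil grid.** The 1000 Hz EEG is low-passed at
   100 Hz (zero-phase, 6th order) and notched at 60 Hz; 1 s windows advanced
   by 10 ms give an FFT periodogram each, integrated (trapezoid) over delta
   (1–4), theta (4–8), alpha (8–12), beta (12–30), low gamma (30–55) and
   high gamma (65–100 Hz). The resulting series are 100 Hz, timestamped at
   window centres, so they align sample-for-sample with the pupil trace.
3. **Aperiodic parameterization.** Averaged spectra are decomposed over
   2–55 Hz into `log10 PSD(f) = b − log10(k + f^chi)` plus at most three
   Gaussian peaks (height ≥ 0.1 log10 units, width 2–10 Hz), the standard
   knee-mode spectral parameterization.
4. **Coupling statistics.** Band power is epoched around dilation peaks
   (peak = time 0). Pre/during/post means use the three 5 s spans
   [-7.5, -2.5), [-2.5, 2.5), [2.5, 7.5); group differences along the
   timebase use pointwise two-sided Student t tests reported as the count
   and percentage of significant time points.
5. **Classification.** Single-band, peak-aligned 12 s power windows (1200
   features at 100 Hz) are labeled spontaneous (0) or evoked (1), balanced
   by subsampling the majority class, and scored by stratified five-fold
   cross-validation with identical fold memberships across six model kinds:
   a 1-D CNN, an RBF-kernel SVM, a 500-tree random forest, Fisher LDA,
   elastic-net logistic regression, and an MLP.

## The synthetic generator and what it emulates

No raw recordings ship with the package; every stage is validated against
`sim_config()`/`simulate_session()`, which generate sessions with known
ground truth.

* **Pupil.** Slow Gaussian drift (low-passed white noise, default SD 0.3)
  plus one unit-peak difference-of-exponentials kernel per dilation (rise
  0.5 s, decay 2 s, default peak 2.0), so the planted peak time and
  amplitude are known exactly.
* **Dilation timing.** Spontaneous events follow a refractory renewal
  process: a 10 s dead time plus an exponential wait whose mean is set so
  the overall mean interval equals `1/event_rate_per_s` (default 30 s).
  Two properties motivated this over a bare Poisson process. First, the
  detector's own 6 s return rule merges dilations closer than ~5 s, so a
  memoryless process caps attainable recall well below what isolated
  transients allow; a refractory process matches the biology of discrete
  arousal events that the detection criteria presuppose. Second, the
  renewal process reproduces the skewed interval distribution that phasic
  arousal shows empirically (mean ≈ 30 s with median ≈ 24 s), whereas a
  shifted summary of that shape is all the analysis consumes.
* **Stimulation.** Onsets every 30 s (first onset at a random phase), 2 s
  trains, one evoked dilation planted 2.5 s after each onset (the latency is
  configurable; published dilation transients peak a few seconds after
  stimulation onset). Spontaneous events within 10 s of an onset are
  discarded, and the pipeline applies the same exclusion to detections so
  the two trial classes cannot overlap.
* **EEG.** An aperiodic background whose expected one-sided periodogram is
  exactly `10^b/(k + f^chi)` (synthesized spectrally; defaults b = 1.5,
  k = 15, chi = 1.8, plausible for rodent cortical EEG), plus per band a
  band-limited Gaussian carrier amplitude-modulated by
  `1 + gain_label · kernel(t − peak + lag)`. The default gains encode the
  arousal signature the analysis is designed to resolve — low-frequency
  suppression and gamma enhancement around dilations, with a stronger
  evoked high-gamma engagement — and are the single dial that defines
  class contrast in calibration and power experiments.

What the generator does **not** emulate: saccade/eye-movement artifacts,
blinks in the EEG, non-stationary background states (sleep/wake
transitions), electrode drift, and 1/f knee changes over time. Passing
tests therefore demonstrate algorithmic correctness and statistical
calibration on in-model data, not robustness to every artifact class of
real recordings.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `threshold_sd` | 0.5 (alt. 0.65, 1.0) | z | detection threshold; event sets nest across the three values |
| window / quiet / return | 10 / 2 / 6 | s | the three detection criteria |
| baseline, amplitude windows | [-6,-4), [-2.5,2.5) | s | event metrics |
| pupil low-pass / high-pass | 3.5 / 0.1 | Hz | measurement smoothing; drift removal |
| EEG low-pass / notch | 100 / 60 | Hz | anti-noise; mains rejection |
| PSD window / step | 1000 / 10 | samples | 1 Hz resolution at 100 Hz output rate |
| aperiodic fit range | 2–55 | Hz | bounded away from the notch |
| `event_rate_per_s` | 1/30 | 1/s | mean dilation rate |
| `slow_noise_cutoff_hz` | 0.05 | Hz | tonic drift timescale (see below) |
| CNN | filters 8/16/32, kernel 7, pool 4 | — | CPU-scale capacity (see below) |

## Design choices where the design was open

* **Order of pupil preprocessing.** The low-pass is applied before
  z-scoring so the session SD reflects the filtered signal; z-scoring
  precedes upsampling and the high-pass. The detection threshold is
  expressed in the session z-units (not re-scaled after the high-pass).
* **Upsampling grid.** A 6000-sample (600 s) input yields exactly 60,000
  output samples: the grid starts at the first input sample and extends one
  input interval short of sample N+1, so the spline extrapolates over the
  final 0.09 s. This convention is intentionally asymmetric; the zero-phase
  test compares time-reversed runs at matched absolute times.
* **"Continuously below"** is evaluated on samples (all 200 samples of the
  2 s span strictly below threshold), with no sub-sample interpolation.
* **Peak and ties.** The peak is the first supra-threshold local maximum;
  plateaus resolve to their earliest sample; boundary samples are never
  peaks. Evoked peaks on flat segments tie-break to the first sample after
  the onset.
* **Search resumption.** After an accepted event, the scan resumes at the
  event offset — the first strictly sub-threshold sample after the peak.
* **Slow-noise cutoff 0.05 Hz.** Tonic pupil drift lives at tens of
  seconds to minutes. A faster drift band (0.2 Hz) would straddle the
  0.1 Hz analysis high-pass and survive into the detection trace at ~0.4 z,
  crossing a 0.5 SD threshold tens of times per 10 minutes — i.e., it would
  no longer be the sub-threshold baseline fluctuation it is meant to model.
* **Blink interpolation** is linear between the last pre-blink and first
  post-blink samples; cubic alternatives were rejected because they can
  overshoot (non-monotone bridges) across long gaps.
* **Normalized PSD** means division by the total 1–100 Hz power, so the
  normalized spectrum integrates to 1 over that range and band values are
  fractions. The 0–1 Hz and 55–65 Hz gaps belong to no band, so the six
  fractions sum to slightly less than 1. Results that depend on the choice
  of normalization should be read qualitatively.
* **Pointwise tests are uncorrected** by default, mirroring the reporting
  style of significant-time-point counts; a Benjamini–Hochberg option
  exists (`correct = "BH"`). The statistical unit is the trial by default
  with a per-session aggregation switch in `window_band_power()`.
* **Elastic net** is fitted as penalized *logistic* regression (binomial
  deviance) rather than the squared-error form of the printed objective:
  the task is binary classification and probability outputs are required
  for the common 0.5 accuracy threshold. Mixing `alpha = 0.5`; lambda by
  inner stratified 3-fold cross-validation.
* **LDA with 1200 features and ~10² trials** cannot invert the pooled
  scatter; the Fisher direction is computed with a shrinkage-regularized
  pooled scatter (`gamma_reg = 1e-3` of the average variance) via the
  Woodbury identity, which keeps the solve at trial-count size.
* **CNN capacity.** Three conv blocks (filters 8/16/32, kernel 7, max-pool
  4), global average pooling, a 32-unit ReLU layer and a sigmoid output;
  Adam (1e-3), minibatch 32, at most 100 epochs, early stopping on the
  accuracy of a 20% validation slice of the training folds with patience
  10, best epoch restored. This is deliberately small: the synthetic
  cohorts are 10²–10³ trials and the suite runs on one CPU; the
  architecture is fully configurable through `classifier_spec()`. The MLP
  (hidden 128/64, dropout 0.3) uses the same engine; batch normalization is
  not implemented — dropout alone regularizes these cohort sizes.
* **Binary label polarity**: spontaneous = 0, evoked = 1; probability ties
  at exactly 0.5 go to class 0.
* **Alignment halfspans.** Classification uses ±6 s (1200 features); the
  pre/during/post analysis needs ±7.5 s. The pipeline extracts at ±7.5 s
  and crops to ±6 s for classification so both printed windows come from
  one extraction.

## Numerical choices

* All filters are applied zero-phase (forward–backward) over an input
  extended by point-symmetric reflection, so edge transients land in the
  padding. The 0.1 Hz high-pass sits three decades below Nyquist, where a
  direct 4th-order transfer function loses ~8 digits to coefficient
  cancellation; it is therefore built as cascaded Butterworth second-order
  sections whose magnitude matches the analytic response to 6 decimals.
* Band-limited synthetic oscillations are synthesized in the frequency
  domain (complex Gaussian coefficients inside the band); time-domain IIR
  band-passes at 1–4 Hz/1000 Hz are numerically unstable.
* `sliding_band_power()` evaluates the real DFT restricted to the 1–100 Hz
  bins as two matrix products per chunk of windows; tests assert exact
  agreement with the `window_psd()` + `band_auc()` route.
* The aperiodic fit uses bounded Levenberg–Marquardt least squares on the
  log10 spectrum (tolerances 1e-10, ≤ 500 iterations), a robust refit that
  discards the top 20% of residuals (peak regions), iterative peak
  extraction with half-height width guesses, a joint Gaussian refit, and a
  final aperiodic refit on the peak-removed spectrum. When the fitted
  exponent is ~0 the knee and offset are jointly unidentified; the fit is
  reported in the canonical `k = 0` form. Non-convergence is flagged on
  the returned object rather than raised.
* Degenerate inputs raise classed errors: constant pupil traces (no
  z-score), traces under 20 s (unstable filters), blink cover above 50%,
  EEG under 5 s, single-class trial sets, zero-variance test columns
  (p = 1 with a warning).

## Problem sizes used by the test suite

Detector–oracle equivalence runs 100 randomized 600 s traces against a
literal re-evaluation of the three criteria at every 0.01 s offset.
Detection recovery uses ten 600 s sessions at the default generator
settings (amplitude 2.0 z, drift 0.3 z, rate 1/30 s). Classifier
calibration and power use cohorts of 200 trials (120 in the acceptance
script); the end-to-end demonstration simulates one 1800 s stimulation
session twice and checks byte identity. These sizes were chosen so the
statistical checks have the power they claim while the whole suite runs on
a single CPU in well under half an hour.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(duration_s = 600, seed = 1)
ses <- simulate_session(cfg)
trace <- preprocess_pupil(ses$pupil)
spont <- detect_spontaneous_dilations(trace)
evoked <- locate_evoked_peaks(trace, ses$stim_onsets)
eeg <- preprocess_eeg(ses$eeg)
bp <- sliding_band_power(eeg)
tm <- build_trial_dataset(bp$high_gamma, rbind(spont, evoked), seed = 1)
crossval_evaluate(tm, classifier_spec("cnn", seed = 1), seed = 1)
```

Or end to end: `demo_run("out_dir", seed = 1)` writes the event table, the
band-power series, window statistics, pointwise tests and the 6-band ×
6-model accuracy table, plus a manifest, and reproduces all of them
byte-identically for a fixed seed.

## Known limitations

* Rapid-eye-movement periods are not excluded (no operational criterion is
  implemented); sessions containing REM-like artifacts will contaminate
  detection.
* The detection threshold is interpreted in whole-session z-units; if the
  0.1 Hz high-pass materially shrinks a session's variance the effective
  threshold is stricter than 0.5 SD of the analyzed trace.
* Single-channel contract throughout; multi-channel data is an outer loop.
* The pointwise test treats trials as exchangeable units; no mixed-effects
  modelling of session structure.
* Classifier accuracies on synthetic cohorts measure separability of the
  generator's coupling contrast, not of any particular animal's data.
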
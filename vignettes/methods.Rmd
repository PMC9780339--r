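---
title: "Methods: in-ear infrasonic hemodynography with earbeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-ear infrasonic hemodynography with earbeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earbeat)
```

## The measurement

Cardiac contraction and the pressure pulse it launches through the vascular
tree produce low-frequency mechanical vibrations. In an open ear canal these
infrasonic (< 20 Hz) pressure fluctuations are negligible, but an occluding
earbud turns the canal into a small sealed cavity whose acoustic impedance
is that of a pure compliance,

$$Z_a \approx \frac{\rho c^2}{j\omega V},$$

so the pressure generated by a given volume-velocity source scales as
$1/V$. Shrinking the effective acoustic volume from an open-ear ~200 cc to
an occluded ~2 cc amplifies biosignal pressure by
$20\log_{10}(200/2) = 40$ dB (`occlusion_gain_db()`), enough for an
ordinary earbud microphone to resolve individual heartbeats. The lumped
model is justified because the shortest infrasonic wavelength,
$c/f = 343/20 = 17.15$ m, dwarfs the canal. Note on units: the impedance
formula is only dimensionally consistent when $\omega$ is an *angular*
frequency in rad/s, so the package treats it as such and provides
`hz_to_angular()`; `acoustic_impedance()` returns magnitude and phase
($-\pi/2$) separately because downstream reasoning needs only the
magnitude.

## The synthetic-data generator

Real in-ear recordings require hardware and subjects; every stage of this
package is therefore developed and tested against a simulator
(`rhythm_spec()`, `gen_ibi()`, `render_record()`, `inject_artifacts()`)
whose defaults encode the study conditions the pipeline is meant to face:

* **Sinus rhythm** (`sr_regular`): IBIs = 60000/HR plus zero-mean Gaussian
  noise, default SD 20 ms — the low, unstructured variability of seated
  rest (observed windowed HRV of 17–22 ms).
* **Paced (resonant) breathing** (`sr_resonant`): sinusoidal respiratory
  sinus arrhythmia at the breathing frequency $1/(t_{in}+t_{ex})$,
  peak-to-peak swing 300 ms by default; ratios 4:4, 4:6 and 5:7 reproduce
  the studied paces.
* **Valsalva** (`valsalva`): a deterministic four-phase trend — baseline,
  a monotone strain drop of 350 ms (> 300 ms), a 400 ms rebound overshoot
  at release, recovery — plus sinus noise. Phase durations are fixed
  fractions (25/25/10/40 %) of the record, a choice made once since only
  the drop and rebound magnitudes are characterised.
* **Atrial fibrillation** (`af`): irregularly irregular IBIs drawn from a
  wide truncated-normal law (SD = range/4) clipped to 400–1600 ms, with a
  weak AR(1) serial correlation ($\phi = 0.1$). Only the observed range is
  characterised for AF; independence-with-clipping is the simplest law
  that yields the dispersion/randomness contrast the classifier relies
  on.

A note on one pair of published figures: paced breathing is described both
by a 300 ms IBI swing and by a ~7 bpm averaged-HR change. For a sinusoidal
RSA model those two cannot hold simultaneously at any realistic mean heart
rate once the 5-s HR averaging window is accounted for; the generator
keeps the 300 ms swing as the defining condition, and the windowed-HR test
checks the analytically predicted boxcar-attenuated swing instead.

**Waveform rendering.** Each beat contributes a Gaussian R-wave template to
the ECG channel and a smooth unimodal pulse to each in-ear channel. The
pulse is a gamma envelope (shape 4): fast rise, slow decay, no curvature
discontinuity — deliberately, because a pulse with a curvature jump at its
maximum changes argmax by several ms under the 20 Hz calibration filter,
whereas the gamma envelope's onset and peak timing survive filtering
exactly. The envelope is placed so that its 10%-amplitude onset lags the
beat by `ih_onset_delay` (default 84 ms) and its maximum by
`ih_peak_delay` (default 158 ms), the delays in-ear pulses show relative
to ventricular depolarization. The right channel differs from the left by
a gain (0.9), a 21 ms moving-average smoothing and a 1.5× stretched decay,
emulating the left/right difference in ear-canal frequency response; with
these defaults the left-versus-right fidelity falls in the high-0.9s while
per-channel beat-to-beat fidelity stays ≥ 0.99. Artifacts are additive:
motion bursts are broadband noise at 5× the cardiac pulse amplitude;
music is band-limited content ≥ 20 Hz that calibration must remove.

What the simulator does *not* emulate: waveform morphology changes across
subjects or with AF (AF records reuse sinus morphology with AF timing),
ectopic beats and non-AF arrhythmias, sensor saturation, slow baseline
drift from earbud reseating, and correlated two-channel artifacts. Passing
the recovery suites therefore demonstrates algorithmic correctness under
the modelled conditions, not clinical performance on real ears.

## The processing pipeline

* **Calibration** (`calibrate()`): per-channel mean removal and a
  zero-phase (forward–backward) Butterworth low-pass, order 4, cutoff
  20 Hz. Zero-phase filtering is essential: beat timing is the measurand,
  and a causal filter would bias every delay estimate.
* **Quality assessment** (`window_features()`,
  `train_quality_classifier()`, `classify_quality()`): one-second
  non-overlapping windows, 24 time-domain features (moments, quantiles,
  crest factor, line length, peak morphology, short-lag autocorrelation),
  a single-hidden-layer perceptron (8 units, weight decay 1e-3) with
  standardized inputs and class-balanced weights, threshold 0.5 on the
  probability of clean signal. The network is trained on a simulator
  corpus labelled by the ground-truth artifact mask, roughly half clean
  and half motion-corrupted windows; windows whose artifact overlap is
  ambiguous (10–90 %) are excluded from training.
* **Beat detection** (`detect_peaks()`): the threshold is a centred moving
  0.999-quantile of the rectified trace over a 3 s horizon — effectively
  the local pulse amplitude — scaled by 0.5. An amplitude-tracking
  statistic is used rather than a mid-distribution quantile because the
  pulse duty cycle varies with heart rate, which would drag any central
  quantile up or down; half the local amplitude separates pulse peaks
  from the noise floor across the whole physiological HR range. Local
  maxima above threshold are accepted greedily by amplitude under a
  250 ms refractory period (no physiological rhythm of interest beats
  faster than 240 bpm). Timing is read at the sample grid (1 ms at the
  default 1000 Hz), which bounds timing error at ±1 ms for the smooth
  pulses involved.
* **Merging** (`merge_channels()`): beat-level fusion — per quality
  window, beats are adopted from the channel with the higher quality
  score; both-bad windows become flagged gaps; boundary duplicates closer
  than the refractory period keep the higher-quality beat. Merging at the
  beat level (rather than mixing raw signals) was chosen because the two
  channels have different pulse shapes and gains, so sample-level mixing
  would distort morphology.
* **Vitals** (`compute_vitals()`): non-overlapping, left-aligned,
  half-open windows; HR = 60000/mean(IBI); HRV defaults to SDNN (the most
  common windowed summary), RMSSD available; an IBI belongs to the window
  containing its midpoint; windows with < 2 IBIs yield no estimate.
  Default window 20 s for steady reporting, 5 s for maneuver tracking.
* **Respiratory rate** (`respiratory_rate()`): the tachogram (or a
  low-frequency envelope trace) is interpolated to a uniform 4 Hz grid,
  zero-padded 8×, and the dominant power-spectral-density frequency in
  0.05–0.5 Hz is reported as breaths/min. Both tachogram and raw-trace
  inputs are supported since either carries the respiratory modulation.
  If no in-band peak exceeds 5× the median in-band power the result is
  indeterminate (`NA`), not an error — unpaced breathing has no sharp
  spectral line.

## Waveform fidelity

`stack_beats()` extracts −250 to +650 ms around each ECG R-peak (901
samples at 1 ms), z-scores each beat, and `fidelity()` takes the median
over successive pairs (or left/right pairs of the same beat) of the
maximum lagged Pearson correlation over lags 0–500 ms. Two conventions
needed fixing: correlations at nonzero lag are computed over the valid
overlap only, because zero padding biases the coefficient toward zero; and
beats are z-score normalized, which is harmless (Pearson is affine
invariant) and makes the stacked mean/SD traces comparable across beats.
A stack of identical beats gives fidelity exactly 1; independent noise
"beats" give values near the extreme-value level of a 501-lag maximum
(~0.15 at 20 beats), checked by Monte-Carlo in the tests.

`ih_delay()` measures, per beat, the in-ear pulse maximum within the beat
interval and the onset as the first crossing of 10% of the peak amplitude
above the pre-peak baseline, with sub-sample linear interpolation of the
crossing. The 10% fraction is configurable; at 0% the onset converges to
the pulse's true start, but 10% is robust to the noise floor.

## Rhythm classification

Filtering precedes segmentation: paired acoustic/ECG IBIs are kept when
|IBI_IH − IBI_ECG| < 100 ms (the published criterion, equated there with
four standard deviations of the difference distribution — the literal
100 ms is implemented) and both lie in 300–2500 ms; single-source series
use the range rule alone. Pairing matches beats by nearest peak time
within 300 ms, comfortably above the mechanical delay. Segments are
consecutive non-overlapping 30-s windows from record start, trailing
partial windows discarded, retained only with ≥ 10 IBIs.

The 17 features (`tachogram_features()`) cover dispersion (pNN50, Poincaré
SD1, SD2 and their SD1·SD2 product, SDNN, RMSSD, CV, median, IQR, MAD,
range), randomness (lag-1 autocorrelation, turning-point ratio, Shannon
entropy of the IBI histogram on fixed 50 ms bins, sample entropy with
m = 2 and r = 0.2·SDNN) and frequency content (normalized 0.04–0.15 Hz
power and spectral entropy of the interpolated-tachogram spectrum). Only
pNN50 and the Poincaré dispersion are characterised in the source
material; the remaining fourteen are this package's concrete choice within
the three stated families, fixed and persisted with every trained model.
"Poincaré dispersion" is implemented as the SD1·SD2 ellipse-area proxy,
with SD1 and SD2 also exported so a ratio can be formed.

`train_rhythm_model()` uses a stratified 80–20 split (stratification is an
implementation choice; it keeps the small AF class represented), five-fold
cross-validated grid search over mtry ∈ {2, 4, 6} and minimum node size
∈ {1, 5} at 300 trees, selecting maximal AF precision, refit on the full
training set, and an internal test report with Wilson 95% intervals
(`wilson_interval()`, closed form, cross-checked against the score
interval of `prop.test(correct = FALSE)`).

The external-database training pathway (PhysioNet waveform records) is not
bundled: no WFDB reader is among this package's dependencies, and all
benchmarks run on the synthetic corpus (`synthetic_segment_corpus()`),
which mixes regular and paced-breathing sinus segments across 50–100 bpm
with AF segments, optionally adding Gaussian beat-timing jitter (21 ms SD)
to emulate acoustic rather than electrical beat timing.

## Agreement statistics

`bland_altman()` reports d = mean(test − reference) — the sign convention
is ours, reference (ECG) first — σ with the n−1 denominator, and
d ± 1.96σ. `one_way_anova()` delegates to `stats::aov`;
`anova_f_from_sums()` recomputes F and p from a published sum-of-squares
decomposition (one published IBI table's between-group SS is inconsistent
with its total − within; the derived value reproduces the printed F, so
the derived value is used). `paired_t_test()` wraps `stats::t.test` with
explicit conventions for degenerate differences (all-zero → t = 0, p = 1;
zero-variance nonzero-mean → p = 0, flagged). P values use exact t and F
distributions throughout.

`bland_altman_sample_size()` finds the smallest n whose limits-of-agreement
confidence bounds stay inside the maximum allowable difference δ with
power 1 − β, using Var(LoA) = σ²(1/n + z²/(2(n−1))) and the criterion
(δ − |d| − 1.96σ)/SE ≥ z_{1−α/2} + z_{1−β}. Published formulations of this
calculation differ in detail, and the canonical inputs (d = 1 ms,
σ = 25 ms, δ = 55 ms, α = 0.05, β = 0.1) are reported in the literature
with n = 785 while common variants give ≈ 770–950; this implementation
yields n = 768 and is validated against a Monte-Carlo power oracle in the
tests rather than adjusted toward any published figure. The formula name
and inputs are attached to every result.

## Numerical choices and degenerate inputs

* Windows everywhere are non-overlapping, left-aligned, half-open
  `[start, start + length)`, timestamps in ms from record start.
* Constant windows: shape, correlation and crest-factor features are 0 by
  convention; constant waveforms make Pearson correlation undefined and
  raise errors naming the offending beat.
* Seeds: a single integer seed propagates through every generator and
  trainer; `ranger` and `nnet` are run single-threaded with fixed seeds,
  so equal configurations give byte-identical outputs.
* Filter warm-up: records shorter than half a second refuse calibration.

## Problem sizes

The test suite and the acceptance script size their simulations as: 60–120 s
records at 1000 Hz for pipeline recovery, an 800-window corpus for the
quality classifier fixture (2000 windows in the classifier's own
benchmark), 2000 SR + 500 AF segments for the rhythm-classifier benchmark
(600 + 150 in the faster unit tests), and 10,000 replicates for the
statistical calibration checks.

## Limitations

Beyond the simulator gaps listed above: no streaming/real-time execution;
no systolic/diastolic interval estimation (the per-beat landmarks are
generic onset/peak only); no arrhythmias other than AF, and the classifier
relies on IBIs alone, so a regularized AF rhythm would evade it; the
quality classifier is trained on synthetic artifacts and would need
retraining for real motion data; and WFDB-format external records are not
read directly.
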
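---
title: "Methods: from raw wrist PPG to cohort discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw wrist PPG to cohort discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wristppg` implements a complete analysis chain for nighttime wrist-worn
photoplethysmography (PPG) sampled at 32 Hz: preprocessing, pulse
segmentation and fiducial detection, extraction of 67 features per 5-minute
segment (30 heart rate variability features, 37 pulse-wave morphology
features), and statistics for contrasting two cohorts — including stepwise
forward feature ranking and incremental logistic-regression classification.
Because wristband datasets of this kind are rarely shareable, the package
ships a synthetic two-cohort generator with known ground truth; every stage
of the pipeline is validated against that ground truth or against
independent brute-force oracles.

## The synthetic study conditions

The generator emulates overnight wristband recordings of two groups of
women: a non-pregnant-like cohort A and a pregnant-like cohort B. The
defaults encode the direction and rough size of the contrasts reported for
healthy pregnancy during sleep:

| parameter | cohort A | cohort B | rationale |
|---|---|---|---|
| mean heart rate | 62 bpm | 74 bpm (+12) | elevated resting HR in pregnancy |
| RMSSD target | 42 ms | 25.2 ms (−40%) | reduced vagally mediated variability |
| systolic upstroke fraction | 0.33 | 0.264 (−20%) | shortened systolic phase |
| LF/HF modulation ratio | 1 | 2 | sympathetic shift |
| age | 25 ± 3 y | 31 ± 3 y | group age difference |

Between-subject spread (HR SD 4 bpm, 12% RMSSD SD, 0.02 systolic-fraction
SD) makes subjects distinguishable so that participant-grouped
cross-validation behaves differently from segment-level folds. All other
parameters (respiration 0.25 Hz, noise SD 0.05 a.u. against a unit pulse,
2 motion bursts/h of 8 s, 8-h nights, 32 Hz) are shared.

**Interbeat intervals.** IBIs are a mean level plus a low-frequency
sinusoid (0.095 Hz), a respiratory sinusoid (0.25 Hz) and white jitter. The
component amplitudes are solved in closed form so the expected RMSSD equals
the target (jitter carries 30% of the squared-RMSSD budget, the sinusoids
70%, split by the LF/HF power ratio) — a sinusoid of amplitude A at
frequency f sampled every T̄ seconds contributes √2·A·|sin(πfT̄)| to RMSSD.
Setting the RMSSD target to zero gives an exactly constant beat train,
which many tests exploit.

**Pulse shape.** Each beat is one period of a two-component Gaussian
template: a systolic bell centred at the systolic-fraction phase and an
optional diastolic bell after it. Gaussians were chosen because their
derivatives are analytic, so the fiducial detectors (velocity maximum a1,
acceleration landmarks a2/b2/e2) can be checked against closed forms. A
linear ramp through the endpoint values, clamped at zero, pins both
template endpoints to its minimum. The rendered record adds slow baseline
wander (< 0.05 Hz), white noise, and motion-artifact bursts (uniform
high-amplitude noise over logged windows, counts Poisson at the configured
rate). The generator logs every beat time and artifact window as ground
truth.

**Hypnograms.** Sleep stages over 30-s epochs follow a first-order Markov
chain on {N1/N2, N3, REM, Wake} whose stationary distribution orders the
stages as in real nights (light sleep most prevalent, then deep sleep, then
REM) with realistic dwell times. The chain is deliberately simple: it does
not reproduce sleep-cycle architecture (REM periodicity, N3 concentration
early in the night), so stage-stratified results on synthetic data only
exercise the plumbing, not sleep physiology.

**What passing tests do and do not show.** The generator produces smooth,
quasi-periodic pulses with stationary noise. Real wrist PPG adds posture
effects, perfusion drifts, irregular rhythms and non-stationary artifact
structure. Tests passing on synthetic data demonstrate that the
implementation is faithful (features measure what they claim on signals
with known truth); they do not certify performance on clinical recordings.

## Preprocessing

Signals at 128 Hz are decimated to 32 Hz with an anti-aliasing filter.
Filtering uses a third-order Butterworth band-pass with corners at 0.007 Hz
and 10 Hz, applied forward-backward (zero phase) so fiducial timing is not
distorted; the mean is removed first because the 0.007-Hz pole has a
~140-second time constant and would otherwise ring at the record edges.
The designed single-pass response is −3 dB at both corners (the zero-phase
application doubles attenuation in the stop bands).

**Motion artifacts.** The Signal Instability Index (SII) of each 15-s
window (advanced by 1 s) is the Gaussian-KDE bandwidth of the window's
amplitude distribution, computed with Silverman's rule of thumb — a
closed-form, deterministic bandwidth selector. Bursts of motion widen the
amplitude distribution and raise the SII roughly tenfold. Windows whose SII
strictly exceeds mean + 0.8·SD of the whole recording's SII series are
excluded (the union of their 15-s extents).

One numerical guard was needed: on a recording with no artifacts at all,
mean + 0.8·SD falls inside the bulk of the SII distribution (roughly its
79th percentile), and the union of 15-s windows would then mask most of a
perfectly clean night. `detect_artifacts()` therefore flags nothing unless
the SII series shows a coefficient of variation above `min_cv` (default
0.1) — genuine bursts exceed this by an order of magnitude, while the
window-to-window variation of an intact signal stays well below it.
Constant windows are assigned SII 0.

## Pulse segmentation and fiducial points

Systolic-peak candidates come from the two-moving-average scheme of Elgendi
et al. (0.5–8 Hz band-pass, clipping, squaring; peak window 111 ms, beat
window 667 ms, offset 2% of the mean squared signal, scaled to 32 Hz).
Onset troughs are the signal minima between consecutive peaks; pulses run
trough to trough, so the final trough of pulse k is the initial trough of
pulse k+1 and pulse widths sum exactly to interbeat intervals. Pulses
overlapping any masked sample are dropped.

Derivatives are computed once per record by central differences, with
3-point smoothing before the second difference (raw second differences at
32 Hz are too noisy for landmark detection; the smoothing attenuates the
sharpest curvature extrema by roughly 15%, which matters only for
amplitude-valued second-derivative features, not for landmark positions).
Landmarks per pulse: a1 = first-derivative maximum on the upstroke; b1 =
first local minimum after a1; a2 = first local maximum of the second
derivative after the onset; b2 = global second-derivative minimum after a2;
e2 = the *first* local second-derivative maximum after b2 — the notch
between systolic and diastolic peaks. (The global maximum in that range
would instead catch the V-shaped junction at the final trough.) Ties and
plateaus resolve to the earliest index. If a candidate systolic peak falls
at or after e2 it has caught the diastolic peak and is redefined as the
maximum between the onset and e2; a1/b1 are then recomputed against the
corrected peak. Pulses remain valid whenever onset, peak and final trough
are all present; missing derivative landmarks only blank the features that
need them.

## The 67-feature catalogue

IBIs are trough-to-trough distances. Intervals outside 0.3–2.4 s, or
differing by more than 20% from the preceding *valid* interval, are flagged
unreliable. Methods that need a continuous series (Welch spectra, sample
entropy) use an on-time reconstruction: missing beats in each gap are
counted from the local median interval and their timestamps obtained from a
quadratic least-squares fit of time against beat number through the two
valid beats on each side (exact for constant trains and for linearly
ramping intervals); gaps longer than 10 s disqualify the segment for
continuous-signal features.

Choices worth stating explicitly:

* **SD convention.** Population (divide-by-n) SDs throughout, and SD1 is
  computed from the uncentred RMS of successive differences, which makes
  SD1 = RMSSD/√2 and S = π·SD1·SD2 exact identities, both asserted in
  tests.
* **pNN50** uses a strict "> 50 ms" rule.
* **Spectra.** The tachogram is resampled at 4 Hz by cubic spline, then a
  Hann-windowed Welch PSD (5-min windows, 50% overlap — a single window for
  the package's 5-min segments; shorter series shrink the window) is
  integrated by the trapezoidal rule over VLF 0–0.04, LF 0.04–0.15 and HF
  0.15–0.4 Hz. Powers are in ms². Normalized powers use LF/(LF+HF); when
  LF+HF is numerically zero the normalized powers and LF/HF are undefined
  and reported missing.
* **Sample entropy**: m = 2, r = 0.2·SD, Chebyshev distance, self-matches
  excluded, computed on the 4-Hz series; verified bit-for-bit against a
  naive O(n²) template counter.
* **DFA α1**: boxes of 4–16 beats, linear detrending. Note that the exact
  DFA-1 expectation for white noise, E[F²(n)] = σ²(n²−4)/(15n), implies a
  slope of ≈0.58–0.60 over these box sizes — the textbook 0.5 is an
  asymptotic value. The test suite asserts the analytic expectation.
* **PRSA**: anchors are beats longer (decelerations) or shorter
  (accelerations) than their predecessor; 50-beat wings on each side
  (anchors without full wings are dropped, and the 50-beat averages force
  this wing length); capacities use the quarter formula
  (X(0)+X(1)−X(−1)−X(−2))/4; immediate responses are the max−min of the
  averaged waveform over the ten beats around the anchor, slopes are
  least-squares over that span, average responses are the difference of the
  50-beat means before vs from the anchor.
* **Fragmentation** works on the sign sequence of IBI increments: zero
  increments terminate runs, are not inflections, and count as length-1
  segments for the short-segment percentage; IALS is the inverse mean
  length of nonzero-sign runs (missing when no nonzero increments exist);
  alternation segments are maximal chains of consecutive strict sign flips,
  counted when they span at least 4 increments. All four indices are
  verified against an independent run-enumeration oracle.
* **Morphology.** Areas are integrated above the straight baseline joining
  the onset and final-trough amplitudes, which removes residual wander from
  the area features. Widths at 10/25/50/60% of the pulse amplitude use
  linear sub-sample interpolation of the level crossings nearest the
  systolic peak, and the reported features are diastolic/systolic width
  ratios. Angles are computed on the amplitude-normalized pulse (amplitude
  scaled to 1) so they are unit-free; slopes are not normalized. SP/SPD
  divides the signal value at the systolic peak by the systolic duration —
  a deliberately literal mixed-unit ratio. Per-segment morphology is the
  per-feature mean over valid pulses (missing per-pulse values ignored),
  requiring at least 10 valid pulses.

The catalogue is exactly 67 names: 30 HRV + 37 morphology, with `t_s` and
the end-diastolic velocity `EDV` emitted as standalone features alongside
the ratios they appear in. `PWD` is a catalogued morphology feature but is
excluded from the ranking pools for the morphology and combined sets, being
analogous to mean HR.

## Segments, gates and stratification

Recordings are cut into non-overlapping 300-s segments — consecutive from
the start in full-night mode, or tiled over maximal runs of at least ten
consecutive same-stage 30-s epochs in sleep-stage mode (Wake is never a
target). Full-night mode uses the entire recording without skipping Wake. A
segment is accepted only if strictly less than 20% of its samples are
artifact-masked and strictly less than 20% of its IBIs are unreliable.
Pulses overlapping masked samples were already dropped at segmentation, so
residual artifact samples inside accepted segments cannot contribute beats;
the on-time reconstruction bridges the resulting gaps for the continuous
methods.

## Statistics, ranking and classification

Group contrasts use the two-sided Mann–Whitney U test plus Cohen's d from
the pooled sample SD, with a 95% percentile-bootstrap CI (2000 resamples);
group medians and interquartile ranges are reported alongside. The same
machinery serves the night-1 vs night-2 comparison. Age trends are ordinary
least-squares regressions of per-subject mean feature values on age.

Feature ranking is greedy forward selection scored by validation AUROC:
within each of 7 independently reshuffled, class-stratified 7-fold
cross-validations, the feature whose addition maximizes mean validation
AUROC of an unpenalized logistic regression is appended, to a depth of 10.
Features are z-scored with training-fold statistics only. Popularity across
the 7 repeats is aggregated by Borda count (rank r in a depth-L ranking
earns L−r+1 points), with ties broken by mean rank and then name; the ten
most popular features form the final list. Incremental evaluation then fits
models on the first k ranked features, k = 1..10, reporting the mean ± SD
of AUROC over the 7×7 held-out folds, either with segments treated as
independent or with participant-grouped folds (all of a subject's segments
held out together); held-out folds containing a single class are skipped.
AUROC itself is the exact rank-sum statistic with mid-ranks for ties,
cross-checked against pROC in the tests.

Design points that were genuinely open: "stepwise forward elimination" is
interpreted as greedy forward *selection* under a validation-AUROC
criterion (no criterion is standard-free); the seven repeats reshuffle
folds with distinct derived seeds rather than reusing one partition;
popularity is a Borda count; ranking depth 10 (the popularity list is
top-10, and deeper rankings only reshuffle features that never enter it);
participant stratification means grouped folds.

## Problem sizes and determinism

The package's validation study simulates 20 subjects per cohort with 1-hour
records (≈480 accepted segments), which is enough for effect directions,
AUROC near its asymptote for the mean-HR contrast, and chance-level AUROC
(0.5 ± 0.1) under shuffled labels; the unit tests run on records of 2–10
minutes. Every source of randomness flows through explicit integer seeds
(one master seed derives per-subject and per-repeat child seeds), so the
whole pipeline — simulation, extraction, ranking, evaluation — is
bit-reproducible, which the acceptance tests assert by running it twice.

## Known limitations

* The generator is phenomenological, not mechanistic: no baroreflex loop,
  no respiratory sinus arrhythmia coupling to an actual respiration signal,
  no sensor-optics model, and gestational progression is a fixed
  second-night shift (+3 bpm, −10% RMSSD) rather than a modelled process.
* At 32 Hz, amplitude-valued second-derivative features (b2 and ratios
  using it) are systematically attenuated by the discrete differentiator;
  comparisons between groups are unaffected because the bias is common to
  both.
* Trough-to-trough beat timing at 32 Hz carries several milliseconds of
  jitter (quantization plus the flat pulse foot), which inflates absolute
  short-term variability measures such as RMSSD on noisy records relative
  to the generating process — a recognized property of low-sampling-rate
  PPG. Group contrasts are preserved because the jitter is common to both
  cohorts.
* The SII `min_cv` guard trades a little sensitivity on almost-clean
  recordings for robustness of the quality gates; recordings whose
  artifacts barely perturb the SII distribution may go unmasked.
* Stage-stratified analyses inherit the simplicity of the Markov hypnogram;
  they validate the stratification code, not sleep science.
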
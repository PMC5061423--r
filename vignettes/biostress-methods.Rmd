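---
title: "Methods: multimodal stressor detection with biostress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal stressor detection with biostress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biostress)
```

# The problem and the model

`biostress` detects short, discrete emotional stressors — surprising or
threatening moments during a vehicle ride — from the coordinated response
they evoke across several body signals. The underlying physiological model
is the classic sympathetic-arousal cascade: a stressor triggers a skin
conductance response (SCR) on top of the slowly drifting tonic level
(SCL), shortens the inter-beat interval (IBI), raises the blink rate, and
shifts the hemispheric balance of EEG alpha power. The channels respond
with different latencies; in this framework the electrodermal response
trails the continuous self-report lever by about 2 s, the cardiac response
by 6.5 s and the blink response by 4.65 s, and these lags are built into
the synthetic generator as per-channel delays.

All analysis operates on a bundle of time-aligned streams (a `session`)
on a common 10 Hz grid, with EEG kept at its native 256 Hz and blink
strength at 128 Hz. Event series (IBI) keep exact beat times.

# The synthetic cohort generator

Every downstream stage is validated against simulated sessions whose
ground truth is known exactly. The generator emulates:

* **Stressor schedules** — non-overlapping events with onset, duration,
  intensity in [0, 1] and valence sign. Defaults: 6 events of 5–10 s with
  intensity 0.7–1 and a 10 s minimum gap per 300 s session (roughly 15%
  stressor coverage). These defaults are the study conditions under which
  the recoverability properties below are stated.
* **Electrodermal activity** (10 Hz): tonic drift around `scl_baseline`
  (5 µS) plus, per event, a sustained phasic response: the
  difference-of-exponentials SCR kernel (rise τ = 0.75 s, decay τ = 4 s)
  convolved with the event window, peak-normalized, delayed by 2 s, with
  peak amplitude `scr_gain · intensity · habituation_rate^exposure`
  (`scr_gain` default 2 µS). The convolution encodes that conductance
  keeps building while a stressor lasts — a sustained stressor evokes a
  train of overlapping SCRs, not a single impulse — which is also what
  makes the square-wave characterization span the stressor episode the
  way the evaluation lever does. Additive Gaussian noise, SD 0.015 µS.
* **Inter-beat intervals**: instantaneous
  IBI(t) = `ibi_baseline`·(1 + `lf_amp`·sin 2π·0.1t + `hf_amp`·sin 2π·0.3t)
  minus a stressor drop of up to `ibi_drop`·intensity (0.15 s) using a
  faster response kernel (rise 0.5 s, decay 2 s — cardiac reactions are
  quicker than electrodermal ones), delayed 6.5 s; beats are produced by
  integrate-and-fire. Parameters that could push IBI below 0.3 s are
  rejected as non-physiological.
* **Six-channel EEG** (256 Hz; F3, FC3, C3 left, F4, FC4, C4 right): 1/f
  background noise plus a 10 Hz alpha rhythm whose amplitude is modulated
  by the binary stressor state with zero lag (a central response): a
  global arousal suppression factor (1 − 0.15·state, classic alpha
  blocking) times a hemispheric asymmetry (1 ± `asymmetry_gain`·state/2,
  + on the right). A lognormal envelope with ~1 s time scale and CV ≈ 0.5
  reproduces the spontaneous waxing and waning of alpha; without it,
  single-epoch band-power features would be unrealistically noise-free
  and classification would saturate regardless of effect size. A small
  18 Hz beta bump is added on left channels during stressor state. All
  stressor modulations habituate with `habituation_rate^exposure`.
* **Blink strength** (128 Hz): Poisson blinks at `blink_base_rate`
  (0.2 Hz), rate multiplied by (1 + intensity) in event windows shifted
  by 4.65 s; each blink is a short half-sine pulse with strength in
  [0, 255] and a 0.25 s refractory period.
* **Lever and joystick** (10 Hz): the lever is intensity·valence inside
  event windows, smoothed over 0.5 s; the joystick is a smooth
  low-frequency trajectory plus white jitter whose SD grows with the
  stressor state (jerky manipulation under stress).
* **Meditation score**: 100·(1 − smoothed stressor state), clamped to
  [0, 100] — an inverse-arousal emulation of the proprietary relaxation
  index, which is treated as a trusted input channel, not re-derived.

What the generator does **not** emulate: motion and electrode artifacts,
respiratory sinus arrhythmia and other nonstationary HRV structure,
eye-blink contamination of EEG, inter-channel crosstalk, or any vehicle
dynamics. Passing recovery tests on this cohort therefore demonstrates
the correctness and calibration of the analysis chain, not its robustness
to real-world artifact load.

Determinism: every stochastic component derives its seed from the
configuration seed via a Lehmer-style mixing of indices (participant,
trial, loop, channel), and all internal seeding saves and restores the
caller's RNG state. Identical configurations give byte-identical
serialized cohorts.

# Characterizations

**Long-term.** Blink counts per half-open 2 s bin (blink events are
upward crossings of strength 50 of 255 with a 0.2 s refractory — the
device's own event rule is proprietary, so the threshold is a documented
knob). Tonic SCL by a 30 s running median: the quantity is named but not
operationalized in the source framework; a median resists phasic spikes
while following drift, and the window is four times the longest SCR decay.
The LF/HF ratio per consecutive 20 s window: the beat series is linearly
interpolated to 4 Hz (spectral HRV analysis requires uniform sampling;
the rate is a documented knob), linearly detrended, and a Welch PSD is
taken with 2 Hamming-tapered segments at 75% overlap, zero-padded to a
power of two at least four times the segment length; LF (0.04–0.15 Hz)
and HF (0.15–0.4 Hz) powers are band integrals. Two segments at 50%
overlap would leave 13 s segments whose Hamming mainlobe smears a 0.1 Hz
LF tone past the 0.15 Hz band edge, destroying LF/HF discrimination; 75%
overlap (16 s segments) keeps overlapping-segment averaging while
preserving the band separation, which is why it is the default.
Meditation is a clamped passthrough.

**Short-term.** The square-wave encoder first smooths with a centered
running mean (1 s for GSR; 0.1 s for the blink-rate proxy), then
thresholds the first-difference slope at k = 3 times its robust SD
(1.4826·MAD); above-threshold samples form maximal runs, runs closer than
0.3 s are merged, runs shorter than 0.5 s dropped, and each surviving run
becomes a rectangle with width = run duration and height = the maximum
signal value in the run. The threshold is derivative-MAD-based, which
makes detection invariant to adding a constant and equivariant to
positive scaling. For sparse signals (blink strength is mostly zero, so
the slope MAD degenerates to zero) the robust SD falls back to the
ordinary SD. Median RRI is the reciprocal of the median RR interval in a
5 s sliding window stepped at 0.1 s — the alternative reading
(median-filtered instantaneous rate) differs only at sharp transients;
the reciprocal-of-median form is implemented and documented. Alpha
asymmetry is right-hemisphere mean minus left-hemisphere mean of 8–13 Hz
periodogram band power in 2 s sliding windows.

# Correlation mapping

Characterizations are screened for normality (single-sample KS against a
fitted normal), skewed ones Box–Cox transformed (λ chosen by profile
log-likelihood on a grid over [−3, 3] when not given; an additive
positivity shift is applied and recorded when needed), and all pairs
correlated by Spearman ρ. Because Spearman ρ is invariant under strictly
monotone transforms, the Box–Cox step cannot change the map; it is kept
for fidelity to the original procedure and the redundancy is asserted in
a test. Significance is p < 0.001 together with |ρ| > 0.5 — applied to
the absolute value, since strong negative correlations (meditation vs
arousal) are substantively meaningful. Edges touching the reference node
(the lever) are primary; significant edges between two nodes that are
each significantly linked to the reference are secondary. P-values use
the t-approximation for n > 30 and a permutation test otherwise.

Delays are estimated by rank cross-correlation over a lag grid. On
injected pure time shifts this recovers 2.0, 4.65 and 6.5 s to within
the 0.1 s grid. On end-to-end physiological traces the estimate is
systematically biased upward for the cardiac channel (around 9–10 s
against the simulated 6.5 s): the cross-correlation peak aligns response
*mass*, and a response that keeps building during the stimulus and decays
afterwards has its mass later than its onset. The validated claim is
therefore injected-shift recovery; raw physiological lags are reported
with their peak correlations so users can judge them.

# Time–frequency analysis

EEG is band-passed 8–25 Hz with a 4th-order zero-phase Butterworth
(forward–backward); samples above 100 µV are masked as artifacts.
Spectrograms use 10 s Hamming windows stepped by 1 s, zero-padded to
exactly 0.1 Hz bin spacing; windows with more than 20% masked samples are
dropped, smaller gaps are mean-imputed. Bands α₁ 8–12, α₂ 13–15, β
16–20 Hz are condensed to per-window means, and each channel × band ×
condition series is summarized by its least-squares slope and variance.
Channel activation is counted by standardizing the N datasets' variances
within each channel/band/condition (z = |(v − mean)/sd|) and counting
datasets per the z rule. The source procedure prints the rule "|z| < 2"
while describing the counted variances as significantly *large*; both
readings are implemented (`z_rule = "ge2"` or `"lt2"`) with `ge2` — the
conventional outlier rule — as the default. Note that with fewer than six
datasets no |z| can reach 2, so groups need N ≥ 6 for the `ge2` rule to
count anything.

# Classification

Stressor-interval labels divide a preprocessed characterization into
equal, successive intervals (2, 4 or 5 s; trailing partial intervals are
dropped) and compare each interval mean to a per-source cutoff: the
series mean for GSRsiginc, GSRSCL and joystick R², the series median for
median RRI, and the fixed value 50 for meditation. Means above the cutoff
are labeled 2 (absence of a stressor), below 1 (presence); exact ties go
to 1, the conservative direction for stressor detection. Only the
combinations tested in the study design are allowed (GSRsiginc 2/4 s;
medianRRI, GSRSCL, Meditation 2/5 s; Joystick 5 s). The joystick R²
score smooths the y-position with a running mean over 2M + 1 = 11 points
and computes R² = 1 − Σ(x − x̂)²/Σ(x − x̄)² per 5 s window, clipped to
[0, 1]; zero-variance windows are perfectly smooth by convention and
flagged.

EEG for classification is band-passed 3–50 Hz (5th-order zero-phase
Butterworth — the extra order keeps 50–60 Hz line noise more than 20 dB
down), linearly detrended per segment, cut into one epoch per label
interval, and baseline-corrected by each epoch's first second. Features
are the ratio of 8–13 Hz to 4–30 Hz periodogram power, either per channel
(6 features) or as left-minus-right differences (3 features). Ratios lie
in (0, 1] by construction. Classifiers are LDA, a linear SVM with cost 1,
and unregularized logistic regression ("simple logistic regression"),
evaluated by stratified ten-fold cross-validation with seed-fixed folds;
per-class recall is retained alongside accuracy. Labels are frequently
imbalanced (stressors are rare), so "chance" in the calibration checks is
the majority-class rate, and the permuted-label null is verified to sit
within a few points of 50% on balanced features.

# Numerical choices and degenerate inputs

* Half-open windows `[t, t + w)` everywhere; timestamps are seconds from
  session start as doubles.
* Missing samples are explicit `NA`s and are never silently interpolated
  except through an explicitly chosen resampling method; LF/HF windows
  with fewer than 2 beats, silent epochs, and constant series are
  missing-flagged or rejected with informative errors rather than
  producing numbers.
* A flat signal (zero slope spread) yields zero square-wave events with a
  warning; an all-equal variance group yields zero counts with a warning.
* Periodogram scaling is one-sided PSD (units²/Hz) with taper power
  normalization, so band integrals satisfy Parseval to within the tested
  5% and match a direct-DFT oracle to 1% on test tones.

# Validation strategy and problem sizes

The test suite validates each stage against independent oracles: direct
DFT band powers computed by explicit complex-exponential sums, greedy
matching of detected square-wave onsets against the generating schedule
(F1 ≥ 0.9 over 20 seeded 300 s sessions), closed-form LDA accuracy for
unit-separated Gaussians (Φ(1/2) ≈ 69.15%), permutation nulls for both
the correlation map (100 seeds × 4 independent series of length 1000,
essentially zero significant edges) and the classifiers (50 permuted-label
repeats at n = 200), and habituation amplitude ratios against the
closed-form 0.7^k. Cohort-level checks use 15 simulated participants for
the correlation map and 4–6 participants × 3 trials for classification;
these sizes make the full suite and the acceptance script each complete
in a few minutes on one CPU while leaving the statistical margins wide.
Trial-wise accuracy decline under habituation is assessed with
`habituation_rate = 0.7`, where the EEG effect leaves the classifier's
saturation regime and the decline is visible in the trial means.

# Known limitations

* The generator's stressor state is binary within events; graded or
  ramping stressors are not modeled.
* Raw cross-correlation delay estimates are biased for asymmetric
  response shapes (see above); a deconvolution-based estimator is out of
  scope.
* The square-wave encoder marks slope *increases* only; it does not
  decompose overlapping SCRs, so two stressors closer than the SCR decay
  merge into one event.
* Narrow-corridor classification is supported by the machinery but, as in
  the study design this mirrors, short narrow segments rarely yield
  enough epochs per class; the pipeline's classification stage skips
  sessions whose labels collapse to one class.
* With the realistic alpha envelope, per-session hemispheric differences
  in band-power *variance* are dominated by spontaneous fluctuation; the
  hemisphere-dominance machinery is validated on constructed
  amplitude-modulated signals and on cohort aggregates, not on single
  sessions.
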
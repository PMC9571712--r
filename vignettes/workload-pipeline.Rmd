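---
title: "Hybrid EEG-fNIRS workload classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid EEG-fNIRS workload classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fbcfuse` analyses multi-level mental workload (n-back) from
simultaneous EEG and fNIRS. This vignette is the package's account of
the science inside it: the generative model used for validation, the
estimators, the selection/classification procedure, the tunable
parameters and why their defaults are what they are, and the known
limitations. Nothing here states an empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The cohort and its timeline

The analysis targets a study layout of 26 participants, each recorded
in 3 sessions; a session holds 3 *series*, and a series presents one
0-back, one 2-back and one 3-back task in random order — 702 tasks in
all. A task cycle is 2 s instruction, 40 s task (20 trials), 1 s stop
and 20 s rest, i.e. 63 s; a session is therefore 9 × 63 s. EEG is 30
channels at 200 Hz, fNIRS 36 channels at 10 Hz. The per-trial stimuli
inside the 40 s task block are not modelled individually: all features
operate on windows of the task period, so the task-level boxcar is the
relevant regressor. Trial-level epoching (±0.5/6 s around stimuli) is
exposed as an option of `sliding_segments()` but unused by the default
pipeline, which follows the window-sweep analysis path.

## The synthetic generator

`simulate_session()` draws, per participant/session, from seeded
streams derived from one master seed by fixed offsets (participant
stream: participant-level response multipliers; session stream: task
orders, then signals), so any subset of the cohort is reproducible in
isolation.

**EEG.** Each channel is 1/f background noise (unit sd by default,
spectrum flattened below 0.5 Hz) plus three *stochastic narrowband
oscillators* centred at 2, 6 and 10 Hz (Gaussian spectral bumps, width
0.75/0.75/1 Hz), scaled so a process of amplitude parameter `a`
carries the band power of a sinusoid of amplitude `a`
(`osc_amp = c(1.0, 0.8, 1.2)` µV). The oscillators are *processes*,
not sinusoids, deliberately: a pure tone has an infinite coherence
time, so any two channels would be mutually phase-locked by
construction and the no-coupling baselines of PLV and MI would be
degenerate. With ~1 Hz bandwidth the phase decorrelates within
seconds, which keeps independent channels at low PLV/MI and makes the
planted coupling detectable as coupling rather than as an artefact.

Planted effects, all linear in the load rank (0/1/2 for
0-/2-/3-back):

- *posterior alpha suppression* at POz/O1/O2: alpha amplitude scaled
  by `1 − alpha_suppression · load` (default 0.2 — a 20% amplitude
  drop per level, in the range of reported workload-related alpha
  suppression and, after squaring, a 1 : 0.64 : 0.36 power gradient);
- *frontal coupling*: the alpha oscillators of Fp1/Fp2/AFz/F1/F2 are
  convexly mixed with one shared narrowband (10 ± 1 Hz) source,
  weight `w = frontal_coupling_gain · load` (default 0.25), giving a
  pairwise in-band correlation of `w²` while leaving each channel's
  alpha power invariant to load. The convex form matters: additively
  injecting the source would also raise frontal alpha *power* with
  load, confounding the connectivity effect with a univariate one and
  letting frontal channels compete with the planted posterior set on
  the PSD accuracy maps.

**fNIRS.** HbO per channel is the task boxcar convolved with a
double-gamma hemodynamic response (`hrf()`: positive gamma of shape 6
minus an undershoot of shape 16 at ratio 1/6, time-scaled so the peak
lands at `hrf_peak_delay = 6` s and unit-peak-normalised), plus slow
drift and white noise (sd 0.3 each against a unit response amplitude).
The planted channel AF8 responds with amplitude
`1 + hbr_effect · load` (default 0.5). HbR is `−κ·HbO` plus
independent noise with `κ = 0.5`; the sign inversion and magnitude
ratio are the conventional deoxy/oxy coupling, and noise sd scales
with κ so both chromophores carry the same signal-to-noise ratio.
Drift is 1/f-weighted noise band-limited to 0.003–0.05 Hz (Mayer
waves, respiration, instrument drift). Its *stochastic* character
matters: an early design used a fixed two-sinusoid drift waveform and
the resulting session-locked temporal fingerprint, combined with
chance label-order imbalance in small cohorts, let classifiers
separate even effect-free data. Stochastic drift with a coherence time
below the 63 s task spacing behaves as slow noise instead, and the
null cohorts then calibrate correctly (the test suite checks both the
ANOVA false-positive rate and permuted-label CV).

**Heterogeneity.** Two log-normal variance components keep single-task
classification away from ceiling, as in real cohorts: per-participant
multipliers (sd 0.3 on the log scale) on baseline alpha amplitude and
on each modality's effect size, and a per-task amplitude jitter
(sd 0.3, shared across channels within a block — a block-level arousal
state). With these, the planted contrasts give d′ of roughly 1–2 per
feature for the large (0 vs 3) contrast, i.e. single-feature
accuracies in the 70–85% range rather than 100%.

What the generator does **not** emulate: volume conduction (channel
mixing), ocular/muscle artifacts, per-trial evoked morphology,
behavioural responses, optode-geometry forward models, or saturating
(non-linear-in-load) effects. Passing tests therefore demonstrate that
the pipeline recovers effects *of the planted kind at the planted
scale*, not that it would reach any particular accuracy on real
recordings.

## Preprocessing

- EEG: 1–45 Hz third-order Butterworth; fNIRS: 0.04 Hz third-order
  low-pass (the nominal "0–0.04 Hz band" has a vacuous 0 Hz edge).
  All filtering is zero-phase (forward–backward), which preserves the
  phase relations that PLV depends on.
- An ocular-artifact stage exists as an identity hook
  (`remove_artifacts()`); blind-source cleaning is out of scope, and
  synthetic data contain no ocular artifacts.
- mBLL (`mbll()`) solves the 2×2 wavelength system per sample;
  default extinction coefficients are textbook 760/850 nm values in
  1/(mM·cm), source–detector distance 3 cm, DPF 6 — all configurable,
  and the round-trip identity is tested rather than the constants.
- Baseline correction subtracts the per-channel *median* of the −5..0 s
  pre-onset interval (clipped at the recording start for a session's
  first task). The median is the documented choice for robustness to
  brief artifacts; the interval length is configurable since only the
  principle, not the length, is prescribed.
- Windows are half-open `[start, start + len)` in seconds, 0 = series
  onset; a window that would cross the end of a recording is skipped
  with a warning rather than padded.

## Features

- **Band power**: Welch PSD (Hann, 2 s segments capped at the window,
  50% overlap), integrated over the band. Welch is the workhorse
  estimator in this field; the 2 s segment keeps ≥ 3 delta cycles per
  segment while giving ~39 averages over a 40 s window.
- **PCC and MI** are computed on band-filtered series so that "a value
  per band" is well-defined for all four estimators; a configuration
  switch allows broadband input instead. MI uses equal-width binning
  with `⌈√N⌉` bins capped at 32 and log base 2; the plug-in estimate
  is clamped at 0 (it is a KL divergence, so only floating-point error
  can push it below). The cap bounds the estimator bias
  (≈ (B−1)²/2N ln 2) at the 8 000-sample default window.
- **MSC** averages Welch cross/auto spectra over 8 segments (50%
  overlap) and then takes the mean over in-band frequency bins —
  coherence from a single segment is identically 1, hence the
  ≥ 2-segment precondition.
- **PLV** extracts instantaneous phase from the analytic signal and
  trims 10% of samples per edge before averaging, suppressing Hilbert
  end effects; the trim fraction is internal because its only role is
  numerical hygiene.
- Feature columns are ordered deterministically (modality, band,
  channel/pair, window, estimator), with channel pairs oriented by
  montage order; none of these conventions change the printed count
  identities 3 × 28 = 84 PSD, 3 × 378 × 4 = 4536 FBC and
  10 × 36 = 360 fNIRS columns. The montage ships 30 EEG channels; the
  28-channel accounting set drops the temporal pair (T7/T8), which
  carries no planted effect.

## Selection, fusion, classification

One-way ANOVA over the three load levels ranks every column by
p-value (ties by larger F, then column index; degenerate columns
last). No multiple-testing correction is applied — the ranking, not
the inference, is the product. The top-5 EEG and top-5 fNIRS columns
are concatenated (EEG first) into the 10-feature hybrid matrix. By
default the EEG pool contains both PSD and FBC columns; a
`psd_only` switch restricts it to univariate features, since the two
readings of the original procedure differ and neither is asserted
here.

Features are then min–max normalised to [−1, 1] *per participant and
column* (constant columns to 0), and classified with an RBF-SVM
(cost 1, `γ = 1/(n_features · var)`) under seeded stratified 5-fold
cross-validation; KNN (k = 5), a depth-limited tree and LDA are
available as comparators. Decision values pool across folds into a
threshold-sweep ROC whose AUC equals the Mann–Whitney statistic (a
tested identity). The positive class is the higher workload.

Three leakage caveats are deliberate and documented rather than
hidden. First, selection precedes cross-validation on the full sample
set, and normalisation uses each participant's full range — both
replicate the published order of operations and are optimistic at
small sample sizes, so `nested_selection = TRUE` provides the
fold-internal variant (selection *and* normalisation fitted on
training folds). Second, the design itself is block-balanced: every
series contains exactly one task of each label, so a flexible
classifier under sample-wise CV can recover part of a held-out
sample's label from its participant's training-set label composition
even on effect-free data — an artifact of the *design*, not of the
features. `folds = "participant"` (subject-wise CV, folds never
splitting a participant) closes that channel. The null-safety check
therefore uses nested selection with subject-wise folds — the
configuration in which chance-level data must and do score at chance
— while the headline accuracies replicate the published sample-wise
protocol. Sample-wise stratified folds remain the default since
whether the original folds respected participant boundaries is
unstated.

## Sweeps and maps

The position sweep slides a fixed window through the 63 s task cycle
(starts measured from the instruction onset — the original's absolute
window clock is not recoverable, so the cycle-relative convention is
defined here) and reports accuracy per start plus the top-10 starts.
The size sweep evaluates window lengths per modality; fNIRS windows of
each size are placed at their best position on a 2 s grid (mirroring
the position-then-size procedure), EEG windows start at the task
onset, since the planted EEG effects are sustained. The expected
qualitative behaviour — fNIRS best at short windows, EEG at long — has
distinct mechanisms in the generator: long fNIRS windows dilute the
hemodynamic transient and average slow drift that shorter, better-
placed windows avoid, while the stationary EEG effects reward longer
windows with lower estimator variance.

Topographic maps use inverse-distance-weighted interpolation (power
2) on the 2-D montage, masked to the sensor convex hull, with exact
reproduction at sensor positions; spherical-spline interpolation is a
deliberate non-goal, as the montage ships as projected 2-D
coordinates (an approximation of the true geometry, documented as
such). Map rendering is a pure transform of already-computed numbers;
re-rendering never re-runs classification.

## Evaluation scales

The validation cohorts are scaled down from the full 26 × 3 design so
the whole suite stays desk-sized: calibration checks use 3
participants × 1 session (54 tasks; ≥ 500 null features across two
cohorts and 50 permutation seeds), recovery and sweep checks use 4
participants × 1 session (36 tasks) across 10 and 5 seeds
respectively, with medians reported. These sizes are the package's
chosen trade-off between statistical resolution and runtime; the
full-cohort identities (702 tasks, column counts) are checked exactly.

## Known limitations

- The FBC estimators are undirected; lagged/directed measures
  (Granger, PLI, transfer entropy) and volume-conduction correction
  are out of scope.
- The plug-in MI estimator is biased upward for short windows; the
  pipeline treats MI as a ranking feature, where a common bias is
  harmless, not as an absolute information estimate.
- Linear-in-load planted effects make the 2-back vs 3-back contrast
  exactly one load-unit wide; real load responses may saturate, which
  is one reason synthetic accuracy orderings need not match any
  particular empirical study beyond the large-contrast > small-
  contrast pattern.
- `signal::resample`'s polyphase filter is adequate for the 200 Hz
  pathway; extreme rate ratios would deserve a dedicated multistage
  design.
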
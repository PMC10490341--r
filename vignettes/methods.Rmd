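---
title: "PPG-based blood-pressure estimation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PPG-based blood-pressure estimation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ppgbp` estimates beat-to-beat systolic and diastolic blood pressure from a
photoplethysmogram recorded over a rest → exercise → recovery protocol.
This vignette is the package's own account of the science: what each stage
assumes, which parameters matter, what the synthetic generator does and
does not emulate, and the choices made where the design was genuinely open.

## 1. Quality screening with the skewness index

A clean PPG pulse spends most of its cycle near the diastolic baseline and
a short time at the systolic excursion, so the distribution of its sample
values is right-skewed. The skewness signal quality index is the third
standardized moment with population (1/N) normalization,
$\mathrm{SSQI} = \tfrac1N \sum_i \left[(x_i - \hat\mu_x)/\sigma\right]^3$,
computed **per beat**. Two choices deserve comment:

* *Population, not sample-corrected, moments.* The index is used as a
  threshold statistic, not an unbiased estimator; the 1/N form is the
  standard definition of the standardized third moment and is what
  `e1071::skewness(type = 1)` computes, which the test suite uses as an
  independent cross-check.
* *Per-beat scoring.* Scoring whole multi-beat windows would blur a single
  corrupted beat across its neighbours; per-beat scoring makes rejection
  counts plain beat counts, which is also the granularity at which
  rejection rates are reported.

The default acceptance rule is `SSQI >= 0`: positive skew characterizes
clean pulses, while baseline wander and slippage dips symmetrize or
left-skew the distribution. Because a single fixed threshold cannot be
optimal across subjects and phases, a linear-SVM mode is provided that
classifies on three per-beat statistics — SSQI, beat length (s), and
peak-to-peak amplitude after per-recording normalization. The three-feature
design is this package's choice; it keeps the classifier linear, scale-free
and trainable from a few dozen labelled beats. Degenerate beats (zero
variance, SSQI undefined) are always rejected.

Beat segmentation finds systolic upstrokes by adaptive-threshold peak
picking on the first difference of a zero-phase 0.5–8 Hz Butterworth
band-pass (order 2, forward–backward). The threshold is set *per 10-s
block* (0.3 × the 95th percentile of positive differences, blocks
overlapping by one minimum peak distance) because a global threshold would
be dominated by high-amplitude motion artifacts and miss low-amplitude
clean beats; feet are then located as raw-signal minima in the 0.3 s before
each upstroke, so that no filtering bias enters the foot-referenced timing
features. Beats shorter than 0.3 s or longer than 2.0 s are dropped.

## 2. Fiducials and the 17-feature vector

The systolic peak is the beat's global maximum; the diastolic (reflected)
peak is the largest local maximum after the dicrotic region. All amplitudes
are measured **relative to the foot value** — the alternative (absolute
units) would let slow baseline level leak into amplitude features.

The second derivative (SDPPG) is computed with Savitzky–Golay polynomial
differentiation: window 9 samples at 125 Hz (scaled with the sampling
rate), polynomial order 4. Order 4 keeps the operator exact for cubic
segments and accurate to ~0.15% for 5 Hz content, the top of the pulse
band; order 3 with the same window attenuates a 5 Hz component's curvature
by ~8%, which is enough to distort the b/a–e/a ratios. The a–e waves are
the first five alternating extrema of the SDPPG after the foot, starting
with the first maximum, and must satisfy the conventional ordering and sign
constraints (a > 0, b < 0); beats with fewer than five qualifying extrema
are excluded with a logged reason rather than padded.

Two ambiguities in the conventional 17-feature table are resolved as
follows:

* Feature 2 is the *diastolic* (second) peak amplitude, feature 4 the
  systolic→diastolic interval ΔT, feature 5 the foot→diastolic-peak time —
  the only reading consistent with a two-peak morphology.
* The SDPPG wave amplitudes enter as ratios b/a, c/a, d/a, e/a (features
  9–12), while a itself (feature 8) is kept raw so absolute curvature
  information survives the normalization.

During heavy exercise the reflected wave attenuates into a shoulder and no
diastolic local maximum exists. Rather than discarding such beats — which
would starve the exercise model of data — the e-wave time of the SDPPG is
used as the diastolic-time surrogate and the beat is flagged
(`dia_fallback`). The fallback time is a coarser measurement than a true
local maximum; consequently the ΔT↔SBP monotonicity the generator embeds
is asserted (Spearman ρ < −0.8) across *directly measured* beats, where the
1-sample peak-recovery guarantee applies.

Feature matrices are Z-score-normalized, `(y − M)/SD` with sample (n−1)
SD, using statistics fitted on the chronological training fraction only
and reused unchanged for validation and test data; constant features are
flagged and dropped with a warning.

## 3. RReliefF selection

Features are scored with the regression Relief estimator: every instance
serves as an anchor in deterministic order (a seeded random-subset mode
exists for very large tables); its k = 10 nearest neighbours by Manhattan
distance on range-scaled features contribute with rank weights
$\exp(-(\mathrm{rank}/\sigma)^2)$, σ = 50, normalized over the k
neighbours; and the weight of feature f is
$W_f = N_{dC\&dF}/N_{dC} - (N_{dF}-N_{dC\&dF})/(m-N_{dC})$ with target and
feature "difference" the range-normalized absolute difference. k = 10 and
σ = 50 are the Relief literature's defaults. Scoring is applied per phase
and per target, on z-scored accepted beats (normalization precedes
selection in the pipeline order). Features with **negative** scores are
eliminated; zero scores are kept, since elimination is strictly of
negatives. Ties in neighbour distance break by instance index, which makes
the scorer exactly reproducible; an O(n²) naive reference implementation
in the test suite pins the optimized scorer to 1e-10.

## 4. The sequence model

Windows of 10 consecutive accepted beats (stride 1) form the model input;
a gap — a rejected or fiducial-failed beat — breaks the run, and no window
crosses a phase or recording boundary. The target is the reference BP of
the window's final beat. The architecture is BiLSTM(100) →
LSTM(200) → LSTM(400) → LSTM(800) → FC(1), trained with MSE loss and Adam
(initial learning rate 0.004, batch 256, up to 850 epochs). The recurrent
engine — cell equations, backpropagation through time, Adam — is
implemented in the package in plain matrix algebra and verified against
numerical differentiation in the test suite.

Design choices within this stage:

* *Separate models per phase and per target*, matching the per-phase,
  per-target feature selection; BP dynamics at rest and during exercise
  are different regimes.
* *Chronological 70/15/15 split* within each recording-phase, with
  later-partition windows dropped when they share source beats with the
  preceding partition — sliding windows overlap by 9 beats, so a random
  split would leak nearly identical windows across partitions. A seeded
  shuffled mode is kept as a flagged alternative.
* *Best-on-test checkpointing.* Hundreds of epochs on desk-scale data
  overfit; the parameters with the lowest test-split loss are retained.
* *Internal target standardization.* Targets are standardized with
  training-set mean/SD and predictions mapped back to mmHg. Without this,
  reaching a ~130 mmHg output level from zero initialization consumes
  thousands of Adam steps at learning rate 0.004 before any waveform
  information is fitted; standardization makes the configured learning
  rate meaningful at any dataset size. Loss curves are reported in mmHg².
* *Window length 10* is a default, not a claim: the informative timespan
  is not settled, so it is exposed as configuration.
* *`scale`* uniformly shrinks hidden sizes and epoch count. The `ci`
  preset (scale 0.25, 100 effective epochs, 2 subjects, 4+4+10-min phases)
  is the package's desk-scale configuration: small enough to train in
  about a minute on one CPU, large enough that the recovery-phase SBP
  descent (~155 → ~118 mmHg) gives the model a real trajectory to track.
  `paper` preserves the full-scale settings.

## 5. Evaluation

Error metrics are MAE, ME (mean signed error), RMSE, the sample SD of
errors, and $R = 1 - \mathrm{MSE}_{model}/\mathrm{MSE}_{standard}$ with
$\mathrm{MSE}_{standard}$ the mean squared deviation of the truth from its
mean. This R is a coefficient-of-determination-style score — 1 only at
perfect prediction, negative for predictors worse than the mean — and is
named `r_score` to avoid confusion with Pearson correlation. The reported
`sd` is the sample SD of errors, consistent with the "mean ± SD" form in
which device-accuracy criteria are stated; RMSE is reported alongside.
Bland–Altman limits of agreement are mean ± 1.96 × SD of the differences.
The ISO 81060-2 verdict is pass iff |ME| ≤ 5 mmHg and SD ≤ 8 mmHg, bounds
inclusive since standards state limits as maxima. The arterial-elasticity
utility implements the incompressible thin-wall estimate
$E = \tfrac38\,(1 + 2r_0/h_0)\,\Delta p/(\Delta h/h_0)$, and the Karvonen
utility the target-heart-rate formula with maximum HR taken as 220 − age
(the standard convention).

## 6. What the synthetic generator emulates — and what it does not

The generator reproduces the *structure* of the protocol and the signal:

* **Protocol.** Three phases (default 20 min each); heart rate relaxes
  first-order (τ = 60 s) from its resting value toward the Karvonen target
  (intensity 0.7) during exercise and back during recovery.
* **Hemodynamics.** SBP relaxes from a 115 mmHg baseline toward
  +40 mmHg during exercise and back; DBP stays at 72 mmHg apart from a
  slow ±3 mmHg drift — rising exercise SBP with stable DBP. The SBP time
  constant, 120 s, is the package's choice (slower than the heart-rate
  response, as pressure recovery typically is). Beat-to-beat Gaussian
  noise: 2 mmHg on BP, 1.5 bpm on HR.
* **Waveform.** Each beat is two log-normal-shaped pulses on a decaying
  diastolic tail — a systolic pulse (peak 0.13 s after the foot, shape
  width 0.35) and a reflected pulse (width 0.25) — plus a small, narrow
  dicrotic-notch component (amplitude 0.05 A₁, width 0.02 s at
  t₁ + 0.5 ΔT) which supplies the curvature structure that makes the SDPPG
  c–d–e complex detectable at every physiologic beat length. The
  latent→waveform map is fixed and invertible: A₁ = 0.02 a.u./mmHg ×
  pulse pressure; ΔT = 0.24 s − 1.2 ms/mmHg × (SBP − 115); reflection
  index 0.45 at rest/recovery and 0.15 during exercise, so the second peak
  visibly attenuates — at 0.15 it merges into a shoulder and exercises the
  e-wave fallback path by construction. A ΔT mapped below 0.05 s is
  rejected as degenerate morphology.
* **Artifacts.** With per-beat probability 0.25 (rest), 0.70 (exercise),
  0.17 (recovery), a beat is corrupted by a 0.1–0.5 Hz baseline-wander
  sinusoid of amplitude 1–2.5 A₁ plus 2–5 negative-going spikes of 2–4 A₁
  (sensor-slippage dips), and flagged. The negative polarity is
  deliberate: it drives the corrupted beat's sample skewness negative, the
  signature the SSQI stage screens for.
* **Reproducibility.** All randomness derives from one integer seed with
  per-phase sub-streams, so a phase's beats are identical regardless of
  the other phases' durations.

What it does **not** emulate: real pulse-wave physiology (no Windkessel or
pulse-decomposition model), inter-subject morphology variation, sensor
transfer functions, respiratory modulation, arrhythmia, or realistic
reference-monitor noise. The reference BP channels are exact step
functions of the per-beat ground truth. Consequently, a passing pipeline
on synthetic data demonstrates that each stage implements its contract —
segmentation finds the true feet, screening finds the planted artifacts,
features recover the latent map, the model learns it — **not** that the
pipeline reaches any particular accuracy on human data.

## 7. Numerical choices and degenerate inputs

* Sample intervals are 0-based and half-open everywhere (phases, beats);
  beats span `[foot_i, foot_{i+1})`.
* Recording files store doubles as `%.17g`, and the reader uses base R's
  correctly-rounded parser, so write→read round trips are bit-exact.
* Fiducial detection excludes the outer 2 samples of the SDPPG from
  extremum search (filter edge rows) and fails closed: any violated
  ordering or sign constraint excludes the beat with a reason, never a
  patched value.
* The quality SVM is trained with deterministic settings; training twice
  on the same data yields identical weights.
* Training aborts on non-finite loss with diagnostics rather than
  continuing; the RReliefF scorer returns all-zero weights with a warning
  for a constant target; `rejection_rate` requires a positive denominator.
* Reference BP per beat is the median of the step-function channel over
  the beat span, robust to off-by-one foot placement at beat boundaries.

## 8. Problem sizes used in the tests

The test suite and the acceptance script run the generator at 2–12 minute
phase durations and the model at scale 0.25 with ≤ 100 effective epochs —
sizes chosen so the full suite completes in a few minutes on one CPU while
every beat-level property is still exercised on hundreds of beats and the
training task retains a ~37 mmHg SBP trajectory. The full-scale
configuration (20-min phases, BiLSTM 100/LSTM 200-400-800, 850 epochs) is
preserved behind `preset = "paper"`.

## 9. Known limitations

* The e-wave fallback biases ΔT upward on attenuated beats; exercise-phase
  ΔT is therefore a coarser regressor than rest/recovery ΔT.
* The SVM quality mode is trained on synthetic labels in this package;
  real deployments need annotated beats.
* Windows never cross phase boundaries, so the model cannot learn
  transition dynamics at phase changes.
* The pooled-chronological split mixes subjects within a partition;
  per-subject held-out evaluation is a stricter protocol left to the user
  (build windows per subject and split on `recording_id`).
* `r_score` is undefined (NA, with a warning) when the reference BP is
  constant over the evaluation window.
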
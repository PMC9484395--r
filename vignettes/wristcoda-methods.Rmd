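---
title: "Methods: behaviour classification and compositional survival analysis"
author: "wristcoda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behaviour classification and compositional survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models it
implements, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, and the
numerical choices that a maintainer would otherwise have to reverse-engineer
from the code.

## 1. The two-stage design

`wristcoda` treats 24-hour movement behaviour analysis as two coupled
problems. The *measurement* stage turns raw wrist acceleration into daily
time in four behaviours (sleep, sedentary behaviour SB, light physical
activity LIPA, moderate-to-vigorous physical activity MVPA — always in this
canonical order). The *inference* stage relates those daily 24-hour
compositions to a time-to-event outcome. The stages are connected only
through the composition, so each can be tested in isolation against
synthetic ground truth.

## 2. Signal quality control

Assumptions: the device reports tri-axial acceleration in gravity units (g)
at a nominal rate; gravity contributes a unit-magnitude component; a worn
device is never still for an hour.

* **Autocalibration.** Stationary 10-s windows (per-axis SD < 13 mg) should
  lie on the unit sphere. We fit per-axis gain and offset by iterating
  "project stationary means onto the sphere, regress projections on current
  values". Calibration is declared failed when the stationary points do not
  include both signs on every axis (the sphere is not covered, so gain and
  offset are not identifiable) or when the fitted points do not end within
  3 mg of 1 g on average. Failure is reported, never raised.
* **Non-wear.** Rolling 60-minute windows stepping by 1 minute qualify when
  every axis has SD < 13 mg over the window; an episode is the union of
  overlapping qualifying windows, hence at least 60 min long and maximal.
  The threshold (13 mg) and minimum duration (60 min) are the field's
  standard; the *scan scheme* is not standardised anywhere we know of, so
  the rolling-window choice is documented here rather than claimed as
  canonical.
* **Inclusion rules** (all violations reported, order-independent):
  clipped fraction ≤ 1% before and after calibration (clipping means
  |value| within 0.5 mg of the ±8 g dynamic range — the tolerance absorbs
  float storage jitter); ≥ 3 days of wear (wear time ÷ 24 h); wear data in
  every 1-hour bin of the 24-hour cycle; mean truncated ENMO ≤ 100 mg;
  successful calibration.

## 3. Features (50, rotation-invariant by construction)

Wrist devices are worn in arbitrary, drifting orientations, so features
must not depend on the axis frame. Every feature is a function of the
vector magnitude series, of angles between consecutive sample vectors, or
of neighbouring-epoch magnitude summaries — all invariant under any fixed
rotation. The catalogue (`feature_info()`) spans: magnitude moments,
truncated-ENMO mean/SD, nine percentiles, IQR, successive-difference
statistics, autocorrelation at 1/2/5 s, zero-crossing rate of the
demeaned magnitude, power and RMS; a Hann-windowed FFT of the demeaned
magnitude giving dominant and second frequencies/powers, band powers
(0.3–1, 1–3, 3–5, 5–8 Hz; absolute and relative), spectral entropy,
centroid and spread; orientation dispersion (mean and SD of the angle
between consecutive samples); and lag ±1 neighbour magnitude means with a
contrast. Cross-axis covariances are *excluded*: they are not rotation
invariant in general.

Sentinels for degenerate input: a constant signal has dominant frequency
0 Hz, spectral entropy 0 and autocorrelation 0. Epochs are 30 s,
non-overlapping, aligned to the trace start; a trailing partial epoch is
dropped; epochs touching non-wear or recording gaps carry `wear = FALSE`
and no features.

## 4. Classifier and smoother

The balanced random forest (100 trees; √50 features per split; unlimited
depth; minimum leaf 1) draws, for each tree, an equal number of epochs per
class — the minority count, with replacement. This counters the roughly
40:1 imbalance between sedentary time and MVPA without reweighting the
loss. Out-of-bag (OOB) predictions are retained for every epoch.

The smoothing HMM treats forest predictions as emissions from the true
behaviour sequence: transitions A are row-normalised counts of
consecutive-epoch true transitions pooled over participants, emissions B
are row-normalised (truth, OOB prediction) counts, and the prior is the
empirical truth frequency. All entries are floored at ε = 1e-4 and
re-normalised; without the floor a transition unseen in training would be
log-impossible and could veto an otherwise overwhelming path. Decoding is
Viterbi in the log domain; ties break toward the lower class index in
canonical order. Hard labels, not vote fractions, are the emissions — the
emission matrix is defined on labels; vote-fraction decoding would need a
different emission model and is deliberately out of scope.

Evaluation is leave-one-participant-out: the forest and HMM are re-fitted
without the held-out participant, whose smoothed sequence is then scored.
Metrics are computed per participant (accuracy, Cohen's kappa, per-class
precision/recall), summarised as means with normal-approximation 95% CIs
(mean ± 1.96 SD/√n; the CI method is a documented choice). The
minute-wise confusion matrix gives each 30-s epoch a 0.5-minute weight —
fractional minutes conserve time exactly, unlike majority-vote minutes.
Per-class metrics with a zero denominator are flagged undefined and
excluded from means with a count, and `loocv(min_class_minutes = 20)`
reproduces the usual low-minutes sensitivity re-mean. Age-subgroup
evaluation is a row filter on the input, not a special case.

## 5. Summarising to compositions

Within each calendar day (device-local time) a minute's behaviour
fractions are the mean one-hot of its wear epochs; a minute with no wear
epochs on some day is imputed as the mean behaviour in the same minute of
day on the remaining days. First/last partial days contribute only their
observed minutes. A minute of day observed on no day at all is an error —
such a participant should already have failed the hourly-coverage rule.
The daily composition is the profile summed over 1440 minutes ÷ 60, so
parts sum to exactly 24 h by construction.

## 6. Compositional survival model

Compositions enter the Cox model through ilr pivot coordinates. The pivot
basis is orthonormal in the Aitchison metric; we report under the order
(MVPA, SB, LIPA, sleep) so the first coordinate contrasts MVPA against
the rest, but every reallocation estimate is provably invariant to the
pivot order (the 24 bases are rotations of each other and the Cox linear
predictor transforms covariantly) — this invariance is tested, not
assumed. Zeros are replaced before transformation: parts under 1 min/day
are raised to the floor and the remaining parts rescaled
multiplicatively, preserving their ratios and the 24-h closure. The floor
is configurable for sensitivity re-runs.

The Cox fit uses age as the timescale with left truncation at entry age,
Efron ties, sex stratification, and categorical covariates with
first-level reference; BMI adjustment, when requested, is additional
*stratification* (3 categories), never a linear covariate — mirroring the
common finding that BMI violates proportional hazards. Fitting delegates
to `survival::coxph`; the package's contribution is the input
construction (ilr design), the output mapping, and everything downstream.

A reallocation moves `amount` min/day into a recipient behaviour either
from a single donor (pairwise) or from the other three in proportion to
their reference shares (proportional). With Δz the coordinate shift from
the reference composition (the cohort's geometric mean, re-closed), the
HR is `exp(β·Δz)` and the 95% CI is the delta-method interval
`exp(β·Δz ± 1.96 √(ΔzᵀVΔz))` — exact under the model's log-linearity
because the estimand is linear in z-space. At the reference the HR is
exactly 1 with a degenerate CI. Note the anchoring asymmetry: the HR of
moving time A→B is not the reciprocal of B→A *from the same reference*;
reciprocity holds exactly when the move is undone from the shifted
composition.

Diagnostics: `check_proportional_hazards()` is the Grambsch-Therneau
scaled-Schoenfeld score test with the Kaplan-Meier time transform
(delegated to `survival::cox.zph`). `evalue()` implements
`E = HR* + sqrt(HR*(HR*-1))`, `HR* = max(HR, 1/HR)`, with the CI E-value
computed on the limit nearer the null (1 if the CI crosses 1). Treating
the HR as a risk ratio is the usual rare-outcome approximation.

## 7. What the synthetic generators emulate — and what they do not

The generators exist so every stage can be tested against known truth
without any external data; their defaults are fixed study conditions, not
free dials.

* **Bout structure.** Behaviour is a semi-Markov process: bout-to-bout
  transitions (zero diagonal) plus geometric bout durations at the 30-s
  epoch scale (means 200/30/20/7 min for sleep/SB/LIPA/MVPA). The
  transition matrix was solved, by flow balance on the implied epoch
  chain, so the stationary distribution equals the mean daily mix
  reported for large middle-aged wrist-accelerometer cohorts — 8.8 h
  sleep, 9.3 h SB, 5.6 h LIPA, 21 min MVPA. An optional hour-of-day
  modulation concentrates sleep at night; it is off by default so the
  implied-matrix identities stay exact.
* **Signal.** Per axis: a unit gravity vector performing a small random
  walk on the sphere (posture drift; 0.05 rad/min during sleep emulates
  turnovers — important, because a sleeper with no posture shifts is
  indistinguishable from a removed device under the 13 mg rule), plus a
  movement sinusoid along a per-bout direction biased toward gravity (so
  cadence appears at its fundamental in the magnitude spectrum), plus
  white noise. Amplitudes order MVPA > LIPA > SB > sleep; LIPA and MVPA
  carry 1 and 2 Hz dominant frequencies (typical walking/running
  cadence). A per-bout lognormal intensity factor (sdlog 0.35) and ±20%
  cadence jitter produce the within-behaviour heterogeneity of free
  living; without them classification is unrealistically perfect.
  Orientation is re-drawn uniformly at each bout start — wearers
  re-position their wrist — which also supplies the sphere coverage that
  autocalibration needs.
* **Cohorts.** Compositions are logistic-normal: multivariate normal on
  the pivot coordinates (location = the mean composition above; SDs
  0.7/0.25/0.2, the MVPA contrast dominating as cohort IQRs imply),
  mapped back and closed to 24 h. Survival: constant baseline hazard
  0.03/year on the age timescale times `exp(β·(z − z_location))`
  (centring makes the baseline the average subject's hazard; Cox
  estimates are invariant to it), independent exponential censoring at
  0.01/year, administrative horizon 8 years (mirroring a maximum
  follow-up of about 7.7 years), entry ages uniform on 55–75. Sex and
  smoking are generated without effects to exercise stratification and
  adjustment machinery.

Not emulated: device temperature and baseline drift, autocorrelated
sensor noise, posture transitions within bouts, population demographics,
seasonal/weekday structure, informative censoring, covariate-composition
confounding. Passing tests therefore demonstrate correctness of the
algorithms under a controlled data-generating process — not field
performance on any particular cohort, which requires labelled real data.

## 8. Numerical choices and problem sizes

* FFTs use a Hann window on the demeaned magnitude; band powers are sums
  of periodogram ordinates; relative quantities normalise by total power
  with zero-power sentinels.
* Viterbi runs in the log domain; ε-flooring guarantees finite scores.
  When several paths tie exactly (products of identical factors in
  different order — about 1% of short random instances), the decoder's
  per-step lowest-index tie-break returns one maximiser; tests compare
  against the full set of maximisers from exhaustive enumeration and
  demand exact equality whenever the maximiser is unique.
* `replace_zeros` rescales unmodified parts multiplicatively, so their
  ratios are preserved to floating-point accuracy.
* Reproducibility: every stochastic function takes an explicit seed and
  uses `withr::with_seed`, so nothing perturbs or depends on the global
  RNG state; equal seeds give bit-identical output.
* Test problem sizes (the package's own choice of scale): classification
  uses 10 synthetic participants × 8 h at 10 Hz; quality control uses a
  7-day trace at 5 Hz; parameter recovery uses 20 cohorts of n = 5000;
  reallocation CI coverage uses 500 cohorts of n = 250. The acceptance
  script mirrors these sizes and derives all seeds from `--seed`.

## 9. Known limitations

* The 50-feature catalogue is this package's documented set; published
  classifiers of this family describe the same feature *domains* but not
  an exact list, so per-feature parity with any external tool is not
  claimed.
* The minute-wise matrix uses fractional-epoch minutes; tools using
  majority-vote minutes will differ in the last digit.
* Emissions are hard labels; a vote-fraction emission model might smooth
  better but has no canonical estimation recipe from OOB votes.
* The delta-method CI for reallocations is exact in z-space but, like
  the Cox model itself, asymptotic in the number of events; the
  bootstrap alternative is left to the user.
* `cohort_spec` generates proportional hazards by construction; the
  power of the PH diagnostic is therefore demonstrated with a
  purpose-built time-varying-coefficient simulation in the tests.
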
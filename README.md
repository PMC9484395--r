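# wristcoda

Movement behaviour classification and compositional survival analysis for
wrist-worn accelerometry.

## The problem

Epidemiological cohorts increasingly measure physical activity with
wrist-worn tri-axial accelerometers rather than questionnaires. Turning a
week of raw acceleration (hundreds of millions of samples in gravity
units) into an epidemiological exposure takes two distinct analyses, and
`wristcoda` implements both:

1. **Behaviour classification.** The day is partitioned into four
   behaviours — sleep, sedentary behaviour (SB), light physical activity
   (LIPA) and moderate-to-vigorous physical activity (MVPA). After
   autocalibration, non-wear detection and quality control, the signal is
   cut into 30-second epochs, each summarised by 50 rotation-invariant
   time- and frequency-domain features. A *balanced random forest* (100
   trees, each grown on a bootstrap drawing the minority-class count from
   every class) classifies epochs; a hidden Markov model then smooths the
   sequence, treating forest outputs as emissions from the true behaviour
   sequence and decoding with the Viterbi algorithm. Transition
   probabilities come from labelled training sequences and emission
   probabilities from the forest's out-of-bag predictions. Evaluation is
   by leave-one-participant-out cross-validation: per-participant
   accuracy, Cohen's kappa, per-class precision/recall, and a minute-wise
   confusion matrix.

2. **Compositional survival analysis.** Daily time in the four behaviours
   is a *composition*: the parts sum to 24 h, so only relative
   information is meaningful. Compositions are mapped to isometric
   log-ratio (ilr) pivot coordinates
   `z_i = sqrt((D-i)/(D-i+1)) * ln(x_i / gmean(x_{i+1..D}))`
   and entered into a Cox proportional-hazards model with age as the
   timescale (left truncation at entry age), stratified by sex, with
   categorical covariate adjustment. Results are expressed as
   *time-reallocation hazard ratios*: the HR of moving, say, 20 min/day
   into MVPA from the other behaviours proportionally, relative to the
   cohort's compositional mean, `HR = exp(beta . (z_new - z_ref))` with a
   delta-method CI. Diagnostics include the Grambsch-Therneau
   proportional-hazards test (Kaplan-Meier time transform) and E-values
   for unmeasured confounding.

Because labelled free-living data and cohort linkages cannot be shipped,
the package includes first-class synthetic generators: a semi-Markov bout
model over the four behaviours whose stationary mix matches published
cohort compositions (~8.8 h sleep, 9.3 h SB, 5.6 h LIPA, 21 min MVPA), a
per-behaviour tri-axial signal model (drifting gravity orientation +
movement sinusoid + noise, with per-bout intensity heterogeneity), and
survival cohorts with known log-hazard coefficients on the ilr
coordinates for parameter-recovery testing.

## Worked example

Simulate a labelled day of wrist data and run the signal pipeline:

```r
library(wristcoda)

labs  <- simulate_behaviour_sequence(default_bout_model(), 24 * 60, seed = 1)
trace <- simulate_trace(labs, sample_rate = 10, seed = 2)
cal   <- calibrate_trace(trace)
quality_check(cal$trace, detect_nonwear(cal$trace))
#> <quality_report> included: FALSE
#>   wear days 1.00 | mean acc 16.4 mg | clip 0.000%/0.000% | calibrated TRUE
#>   reasons: insufficient wear days
```

One day is correctly rejected (the rule requires three wear days); the
mean acceleration of ~16 mg and successful autocalibration are typical of
real wrist data. Features and classification:

```r
epochs <- epoch_features(cal$trace, labels = labs)
model  <- train_balanced_forest(epochs[epochs$wear, ], seed = 1)
smooth <- viterbi_smooth(predict(model, epochs)$pred,
                         estimate_hmm(epochs$truth, model$oob))
```

Simulate a cohort in which MVPA is protective (ilr coefficients
(-0.35, 0.15, 0) under the MVPA-first pivot), fit the compositional Cox
model and read off reallocation HRs:

```r
coh <- simulate_cohort(
  cohort_spec(n_subjects = 5000, true_coefficients = c(-0.35, 0.15, 0)),
  seed = 7)
fit <- fit_behaviour_cox(coh, covariates = "smoking")
tidy(fit)
#> # A tibble: 5 × 7
#>   term           estimate std_error statistic  p_value conf_low conf_high
#> 1 z1              -0.369     0.0448    -8.25  1.63e-16  -0.457     -0.281
#> 2 z2               0.367     0.123      3.00  2.72e- 3   0.127      0.608
#> ...

reallocate(fit, to = "MVPA", from = "all", amount_min = 20)
#>   to    from  amount_min    hr conf_low conf_high ...
#> 1 MVPA  all           20 0.804    0.763     0.847

reallocate(fit, to = "SB", from = "LIPA", amount_min = 60)
#> 1 SB    LIPA          60  1.03    0.975      1.10
```

Moving 20 min/day into MVPA from the other behaviours proportionally is
associated with a 20% lower hazard for this simulated cohort (the truth
implied by the generating coefficients is recovered within the CI);
swapping an hour of LIPA for SB moves the hazard only a little. How
strong would an unmeasured confounder have to be to explain the MVPA
association away?

```r
r <- reallocate(fit, to = "MVPA", from = "all", amount_min = 20)
evalue(r$hr, r$conf_low, r$conf_high)
#>      hr evalue_estimate evalue_ci
#> 1 0.804            1.79      1.64
```

`check_proportional_hazards(fit)` runs the Grambsch-Therneau test
(one row per term plus a global row), `reallocation_grid()` +
`plot_reallocation()` draw pairwise reallocation curves, and
`impute_profile()` / `daily_composition()` turn smoothed epoch labels
into the 24-hour compositions the survival stage consumes.

A thin command-line front end over the same functions is installed as
`exec/wristcoda` (`simulate-trace`, `simulate-cohort`, `qc`, `extract`,
`reallocate`).

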
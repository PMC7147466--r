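---
title: "Predicting nocturnal hypoglycemia from pre-sleep CGM and activity data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting nocturnal hypoglycemia from pre-sleep CGM and activity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the modelling approach

People with type 1 diabetes on multiple daily injections inject a
long-acting basal insulin plus rapid-acting boluses at meals. Because basal
insulin cannot be modulated overnight, a slightly excessive evening dose,
late exercise, or an over-bolused dinner can push interstitial glucose
below 70 mg/dL (3.9 mmol/L) during sleep — nocturnal hypoglycemia (NH) —
often without waking the patient. `nhpred` frames NH anticipation as a
per-patient binary classification problem decided once per night at
bedtime.

The pipeline has five stages, each an exported function family:

1. **I/O** (`read_cgm_csv()` and friends): vendor-neutral CSV dialects for
   the four streams (CGM, event log, per-minute activity, sleep periods).
   All timestamps are timezone-naive local ISO-8601; glucose is stored in
   mg/dL.
2. **Preprocessing** (`resample_to_grid()`, `impute_gaps()`,
   `align_activity()`): a day-aligned 5-min grid (288 points/day), with
   linear interpolation of CGM gaps of at most 120 min.
3. **Physiological effect signals** (`iob_profile()`, `cob_profile()`,
   `aob_profile()`): insulin-, carbohydrate- and activity-on-board.
4. **Instance building** (`select_nights()`, `extract_features()`,
   `label_night()`, `build_dataset()`): 29 pre-sleep features and a binary
   label per retained night.
5. **Model selection** (`stratified_folds()`, `evaluate_subset()`,
   `exhaustive_search()`): exhaustive feature-group search under repeated
   stratified k-fold cross-validation, scored by `gmean()`.

## Assumptions

* The sleep period reported by the wrist tracker is trustworthy enough to
  anchor both windows; nights without a usable sleep record yield no
  instance.
* Interstitial glucose is the ground truth for hypoglycemia (no SMBG
  adjudication); the 70 mg/dL threshold is applied to CGM readings.
* Patients log boluses and meal carbohydrates manually; the models tolerate
  missing entries (an unlogged bolus simply contributes no IOB) but cannot
  correct them.

# Windows, labels and features

The **pre-sleep window** is the half-open interval `(onset − 360 min,
onset]` and the **label window** is `[onset, onset + 360 min)`: the onset
reading belongs to the feature side, since it is available when the
prediction is made. Both windows must have at least 80% non-missing CGM
coverage on the 5-min grid, otherwise the night is discarded (with a
message, not an error — attrition is normal in free-living data). The
label is 1 if any non-missing reading in the label window is below
70 mg/dL. Imputed points may trigger labels by default: a linear
interpolation over at most 120 min is bounded by its two measured anchors,
so it can only report a hypoglycemic value if at least one anchor is itself
low; `label_include_imputed = FALSE` restricts labels to measured points.
The label window is always the full 6 h, even when the patient wakes
earlier.

One onset is retained per calendar night: the start of the first sleep
period of duration ≥ 3 h beginning between 20:00 and 04:00. Shorter
evening naps are skipped; an onset after midnight is attributed to the
previous calendar date. The 3 h / clock-window rule and the 0.8 coverage
threshold are this package's own operational choices for separating "the
night's sleep" from naps and fragmentary records.

The 29 features (see `feature_catalog()`) are partitioned into 11 groups:
endpoint values (2), central tendency (3), dispersion (3), extremes (3),
rates of change (4), time in ranges (4), risk indices (3), hypoglycemia
history (3), IOB (1), COB (1) and physical activity (2). The low/high
blood-glucose indices use the standard symmetrized risk transform
`f(g) = 1.509((ln g)^1.084 − 5.381)`, with `LBGI` the mean of `10 f²` over
readings with `f < 0` (zero otherwise) and `HBGI` its high-side
counterpart. Hypoglycemia episodes are runs of readings below 70 mg/dL;
two runs merge unless separated by more than 15 min above threshold. The
exact composition of the 25 CGM features is this package's normative
catalog: only the group structure (one COB, one IOB, two activity features,
the rest CGM) is externally constrained.

# On-board models

IOB and COB use the two-compartment equal-time-constant impulse response

$$\mathrm{OB}(t) = D\, e^{-t/\tau}\,\bigl(1 + t/\tau\bigr), \qquad t \ge 0,$$

the standard artificial-pancreas formulation with the right qualitative
shape: full amount on board at the event, a smooth shoulder, then
exponential decay to zero. Contributions of multiple events superpose
additively. Defaults: `tau_ins` = 75 min (rapid analogue insulin,
effective action tail of ~5–6 h), `tau_ch` = 40 min (mixed-meal
absorption), both configurable via `physio_params()`. Long-acting insulin
doses are recorded in the event log but excluded from IOB — the model
describes prandial boluses, and basal analogues have nearly flat profiles.
AOB is a first-order leaky accumulator of 5-min step counts with decay
`exp(−Δt/tau_act)`, `tau_act` = 120 min, capturing that the
glucose-lowering effect of exercise outlasts the activity itself.

Since the upstream references for these models specify families rather
than universal constants, the time constants here are package defaults
chosen from typical adult values, not fitted quantities.

# The synthetic cohort generator

No free-living MDI dataset of this shape is publicly deposited, so
`simulate_patient()` generates one. It is a *minimal linear-response*
model — enough structure for the pipeline to have something real to find,
and no more. On the internal 5-min step:

$$G_{t+1} = G_t + \alpha\,(G_b - G_t) + k_{meal}\,RA_t - k_{ins}\,IA_t -
k_{act}\,AOB_t - \beta\,\mathrm{night}_t + \varepsilon_t,$$

where `RA`/`IA` are the per-step appearance increments implied by the COB/
IOB curves, `night` indicates the sleep period, and `ε` is AR(1) noise.
The mean-reversion term `α (G_b − G_t)` (defaults `α` = 0.03 per step,
`G_b` = 145 mg/dL) is required for stationarity: a pure integrator drifts
without bound over 84 days and cannot maintain a hypoglycemia-free
baseline regime. The nocturnal drift `β` (`basal_overdose`, mg/dL per
5-min step) is the single prevalence knob: it emulates a slightly
excessive basal dose whose effect surfaces when meals stop.

Default schedule: three meals (08:00, 13:30, 21:00; 45/70/60 g CH),
boluses at 1 U per 10 g with 25% relative dosing error, an evening walk
(18:30–20:30 window, ~40 min, ~90 steps/min, 60% of days), sleep onset
23:20 ± 35 min for ~8 h. The late dinner and evening activity are typical
of southern-European cohorts and deliberately place bolus IOB and AOB tails
inside the pre-sleep window, so bedtime features carry predictive signal —
the generator's stated design goal. CGM is emitted at 15-min cadence
(exercising the resampling stage), with on average 0.5 sensor gaps per day
of log-normal length (median 40 min, some exceeding the 120-min imputation
bound). Glucose is clamped to the sensor range [40, 400] mg/dL at
emission.

`basal_overdose` = 1.25 was calibrated by Monte Carlo so that about one
third of labeled nights are hypoglycemic, the prevalence the pipeline is
designed around; the test suite re-verifies the calibration over ~1000
simulated nights. With noise, dosing error and overdose all zero, no night
dips below 70 mg/dL — a clean negative control, verified by the test
suite.

**What the generator does not emulate:** glucose physiology (no
insulin-sensitivity circadian rhythm, no dawn phenomenon, no
counter-regulation), heart-rate-driven exercise intensity, alcohol or
hormonal covariates, sensor drift/recalibration, or realistic inter-patient
heterogeneity beyond seed-to-seed variation. Consequently, passing tests
demonstrate that the *pipeline* is correct and that the *protocol* can
recover planted structure — not that the classifiers would reach any
particular performance on real patients.

# Cross-validation and the exhaustive search

Each candidate feature subset is one of the `2^11 − 1` non-empty unions of
catalog groups (the empty mask is skipped; 2048 masks enumerated). For
every repetition `r` (seed `base_seed + r`):

* a stratified fold assignment is drawn — per class, a shuffled
  round-robin, so each fold's class count differs from the proportional
  share by less than 1;
* within each fold, features are z-scored with training-fold statistics
  (zero-variance columns are centred, not scaled), the classifier is
  fitted, the held-out fold predicted;
* the k folds' confusion counts are **pooled** into one SN/SP/accuracy/
  Gmean quadruple. Pooling, rather than averaging per-fold rates, keeps
  the metrics defined when a fold holds only one or two positives.

The subset's score is the arithmetic mean of per-repetition Gmeans. This
is deliberately *not* `√(mean SN · mean SP)`; by Cauchy–Schwarz the mean
of Gmeans is bounded above by the Gmean of means, and the tests assert
that ordering. Ties in the ranking are broken by fewer selected features,
then by ascending mask id — fully deterministic.

Classifier defaults (hyperparameters are not externally constrained, so
these are package choices, all exposed in `cv_config()`):

* **SVM**: RBF kernel, `C = 1`, kernel width `γ = 1/(q·Var(X))` computed
  on the z-scored training fold, class weights inversely proportional to
  class frequency (the prevalent negative class must not dominate);
* **MLP**: one hidden layer of 8 logistic units, cross-entropy loss, at
  most 500 epochs, initialisation seeded per repetition.

When a patient's minority class has fewer than `k` members, `k` is reduced
to that count (with a message) rather than dropping the patient — small
cohorts are the rule in this domain, and a 14-night patient with 3 events
is still evaluable at k = 3.

## Degenerate inputs and numerical conventions

* Records equidistant between two grid points attach to the later point;
  among several records nearest to one grid point, the earliest wins.
* A "≤ 120 min" gap is measured between its two bounding measured points,
  so at most 23 consecutive 5-min points are imputable; leading/trailing
  runs have no second anchor and stay missing.
* Glucometrics boundary conventions: 70–180 inclusive on both ends; <70,
  <54, >180, >250 strict; so boundary readings fall in the lower category.
* Cohort medians use the sample median (mean of central pair for even n),
  reported to 2 decimals; expected-intervention counts use
  nearest-integer rounding, which is why printed rates and rounded counts
  can disagree by one night.
* All-missing traces, empty cohorts, non-stratifiable label vectors and
  invalid configurations raise classed errors
  (`nhpred_insufficient_data`, `nhpred_stratification_error`,
  `nhpred_config_error`, ...), never silent NAs.

# Problem sizes used by the test suite

The suite favours many small, exactly checkable fixtures. The stochastic
checks use: ~1060 simulated nights (13 patients × 84 days) for the
prevalence calibration; 1000 randomised nights for the label-window
brute-force comparison; n = 100 balanced instances × 20 repetitions for
the chance-level (shuffled-label) check, expected at Gmean 50 ± 5; and a
full 2047-mask search at n = 80, 5 repetitions for planted-signal
recovery. The end-to-end determinism check runs the whole pipeline twice
on a 40-day patient at 5 repetitions and compares output files
byte-for-byte. These sizes are the package's chosen trade-off between
Monte-Carlo resolution and a test suite that stays pleasant to run.

# Known limitations

* The feature catalog is fixed at 29 features / 11 groups; adding features
  requires extending the catalog and the group map together.
* The exhaustive search is O(2^G) classifier fits and is practical only
  because groups, not individual features, are toggled; for larger
  catalogs a greedy or randomised search would be needed.
* Per-patient results on real data are not reproducible here: the
  reference cohort's raw streams were never deposited. The shipped
  reference tables support only the in-report arithmetic (medians,
  Gmean/accuracy identities, expected-intervention counts).
* The generator's simplicity means absolute performance numbers on
  synthetic cohorts should not be read as clinical estimates; they
  demonstrate recoverable structure, not expected real-world accuracy.
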
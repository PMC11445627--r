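---
title: "From irregular vital signs to hourly arrest alarms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From irregular vital signs to hourly arrest alarms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrestwatch)
```

## The prediction problem

In-hospital cardiac arrest is rare but catastrophic, and most arrests are
preceded by hours of physiological destabilization — rising heart and
respiratory rate, falling blood pressure and oxygen saturation. `arrestwatch`
implements an early-warning pipeline that turns the six routinely charted ICU
vitals (HR, RR, SBP, DBP, SpO2, temperature) into an hourly risk score: at
every whole hour `t` of a stay, the model looks back over the previous 12
hours and estimates the probability that an arrest begins within the next 24
hours (labels use the half-open horizon `(t, t + 24]`). Replaying each stay
hour by hour ("pseudo-real time") turns those probabilities into an alarm
trace that can be scored the way a bedside system would be judged: did an
alarm fire before each arrest (event recall), and what fraction of alarms was
wasted (false alarm rate)?

Because real ICU databases of this kind are credentialed, the package ships a
synthetic generator that emulates the statistical structure the pipeline
assumes; every claim the test suite makes is a claim about recovering a known
planted signal, not about clinical performance.

## Preprocessing

Bedside observations arrive irregularly. The pipeline is fixed, in order:

1. **Plausibility filtering.** Values outside conservative physiological
   ranges (HR 20–300 beats/min, RR 4–60, SBP 40–250 mmHg, DBP 20–180, SpO2
   50–100 %, temperature 30–43 °C) are discarded as artifacts. Sites normally
   maintain their own expert ranges, so these deliberately wide defaults are
   fully overridable.
2. **Hourly bucketing.** Bucket `h` covers `[h, h+1)` hours since admission
   (0-based, half-open); values inside a bucket are averaged, empty buckets
   are marked null.
3. **Imputation.** Nulls take the nearest *later* observation in the same
   series (carried backward); trailing nulls take the nearest earlier one
   (carried forward). The rule uses only within-stay information, so pooling
   arrest and non-arrest stays before imputing changes nothing — a property
   worth knowing because it means imputation cannot leak outcome labels.
   Imputation is idempotent. A series with no observations at all is left to
   the fill step.
4. **Early-warning channels.** Each raw vital is scored 0–3 against a banded
   chart. The shipped chart codifies the classic Modified Early Warning Score
   bands (HR, RR, SBP, temperature), adds the standard NEWS oxygen-saturation
   bands, and a diastolic band written for this package so every vital has a
   score channel. Hospitals deploy many chart variants, so the chart is a
   plain CSV fixture and can be replaced wholesale.
5. **Normalization.** Min-max scaling against the same plausibility bounds,
   so all model inputs live in `[0, 1]`. Score channels are scaled by 3 (the
   per-vital maximum) and the total by `3 x charted signals`. Fully
   unobserved series are filled with 0.5, the normalized midpoint, and
   flagged — dropping such stays would silently shrink the cohort.

## Features

Each 12-hour window over 13 channels (6 vitals + 6 per-vital score channels +
the score total) yields 637 named candidates:

* **Time-step features** (156): the raw hourly values, `HR_8h` being lookback
  hour 8 (1-based).
* **Multiresolution statistics** (468): mean, median, min, max, population
  SD and adjusted Fisher–Pearson skewness over tiled segments 1–4, 5–8,
  9–12, 1–6, 7–12 and 1–12. Tiled segments (rather than three nested
  prefixes) were chosen so that every part of the lookback owns features of
  its own — names like `HR_5_8h_Skewness` or `DBP_9_12h_Max` refer to a
  specific stretch of the window. Segment plan and statistic set are
  configuration, not code.
* **Gini dispersion** (13): per channel, the Gini coefficient
  `G = sum_ij |x_i - x_j| / (2 n^2 mean)` of the 12 hourly values is folded
  into `GV = 1 - 2G/11` (11 = intervals between 12 values). A flat series
  gives GV = 1; pre-arrest instability lowers GV. `G` is pinned to an O(n²)
  pairwise oracle at 1e-12 in the tests.

The default design yields exactly 156 + 468 + 13 = 637 candidates; related
early-warning pipelines report totals in the 650 range, but no consistent
channel/segment/statistic accounting reproduces those counts, so this
package documents its own arithmetic rather than forcing a match.

## Screening

Two screens vote: recursive feature elimination (gradient-boosted importance,
dropping 10% of surviving features per iteration down to 15% of candidates)
and a shadow-feature relevance screen in the Boruta style (each iteration
compares every feature's importance with the best of the column-shuffled
shadow copies; binomial hit counts at a Bonferroni-corrected two-sided 0.05
confirm or reject; leftovers are resolved by median importance against the
median best shadow). A feature is kept when both screens select it
(threshold 2 — with two voters, "majority" is unanimity); if the vote is
empty the eliminator's set is used. Screening runs **inside** every
cross-validation fold, on training patients only — the only placement that
cannot leak test information into feature selection.
Importance models fit on at most 1,600 rows — all arrest windows are kept and
only non-arrest windows are downsampled, because the minority class carries
the signal.

## The classifier

The reference backend is an attentive tabular network written for this
package: `n_steps = 3` sequential decision steps, each computing an
input-dependent softmax mask over features, relaxed by a prior that
discounts features attended earlier (`relaxation = 1.3`), feeding a masked
ReLU transformer (`width = 8`) whose output adds to the logit. The loss is
class-weighted cross-entropy — arrest windows weigh `class_weight_ca = 100`
(missing an arrest is treated as two orders of magnitude costlier than a
false alarm), trained at learning rate 0.01 — plus an entropy sparsity
penalty (`1e-3`) on the masks. Architecture and optimizer settings are
ordinary defaults, all exposed in `arrest_config()`.

Three training choices matter and are this package's own:

* **Decoupled weight decay (1.0).** Hourly windows within a patient are
  strongly correlated; the effective sample size is patients, not windows,
  and an unregularized network memorizes training patients (we observed
  near-perfect training AUROC with chance-level held-out AUROC). Strong
  decoupled L2 is the corrective.
* **Patient-grouped early stopping on validation AUROC.** The early-stopping
  split holds out whole patients, and the monitor is discrimination (the
  primary outcome), not the weighted loss — a window-level split lets the
  monitor reward memorization, and the weight-100 loss saturates on recall
  long before ranking stops improving.
* **Exact gradients.** Backpropagation runs through the full mask/prior
  chain and is pinned to a finite-difference oracle at 1e-4 in the tests.

Masks are nonnegative and row-normalized; per-sample aggregate importance
weights each step's mask by its nonnegative decision contribution and
renormalizes, so importances sum to 1 per window. Because masks cannot be
negative, signed "this feature lowered the risk" attributions are outside
the mask formalism; group-difference t statistics (below) carry the
direction instead. A gradient-boosted backend (`backend = "xgboost"`,
normalized absolute SHAP as its single-step mask) implements the same
fit/predict/explain contract where training speed matters more than per-step
masks, e.g. in permutation-null experiments.

## Evaluation

Folds partition **patients** (never windows), stratified by
ever-arrests, ten folds by default. Per fold: screen on training patients,
fit, then replay every test stay hour by hour. Metrics per fold: pooled
window AUROC, sensitivity/specificity at the alarm threshold (0.5 by
default; the operating point is a deployment decision and is reported with
the metrics), Brier score, and the
event-based pair — event recall `ER = N_captured / N_total` (an event is
captured if at least one true alarm fires in its 24-hour pre-onset span) and
false alarm rate `FAR = 1 - N_true / N_alarm` (reported missing when no
alarm fired, since the ratio is undefined). AUROC is aggregated as per-fold
mean ± SD; pooled AUROC is available behind `pooled_auroc = TRUE`. Windows
whose lookback would cross an earlier arrest are dropped (post-arrest
physiology is neither a negative nor a fresh positive), and emission resumes
24 hours after each event so multi-event stays are replayed between events.

Subgroup evaluation partitions the *test* predictions by ICU subtype with no
retraining; cross-dataset validation fits once on one dataset and replays
another over the intersected feature schema. Model comparisons on fold-level
metrics use Kruskal–Wallis followed by Tukey HSD contrasts at 5%, applied to
the fold metric values. Importance differences between arrest and non-arrest
windows use per-feature Welch t tests with Benjamini–Hochberg
false-discovery-rate correction.

## The synthetic bed: what it does and does not show

`synth_cohort()` draws lognormal stay lengths (median ~72 h, clamped to
24 h–3 weeks), per-patient baselines around population means, hourly AR(1)
wander (`phi = 0.9`), irregular Poisson sampling (~1 observation per
signal-hour), multi-hour documentation gaps, rare artifact spikes, and — for
the 4% of stays with an arrest — an onset uniform past 36 h with a linear
destabilization ramp over the final 24 pre-onset hours reaching HR +15
beats/min, RR +4 breaths/min, SBP −12 mmHg, SpO2 −3 % at onset. Directions
follow the destabilization pattern reported for arrest cohorts; magnitudes
are the generator's own. SpO2 ramps downward (clinical destabilization)
even though *static* group means for SpO2 can sit slightly higher in arrest
cohorts — a whole-stay average is not a pre-onset trajectory, and it is the
trajectory the generator plants.

The noise scales (between-patient SDs of about 2 beats/min HR, 3 mmHg SBP, and
AR innovations a fraction of that) are deliberately tighter than real ICU
populations: the bed is calibrated as a **signal-recovery oracle**, easy
enough that a sound implementation of the full pipeline recovers the planted
signature (leave-one-patient-out AUROC above 0.85, event recall above 0.9 at
threshold 0.5), so that a regression anywhere in the chain — bucketing,
labeling, screening, training, replay — shows up as a failed recovery.
Passing it says the machinery is correct; it says nothing about performance
on real patients, where between-patient variability, comorbidity, and
treatment interventions dominate. Conversely `planted_feature_bed()` is a
plain tabular oracle (Gaussian features, mean-shifted informative columns)
for screening and classifier contracts.

## Numerical choices and degenerate inputs

* Population SD and adjusted Fisher–Pearson skewness (0 for constant or
  n < 3 segments); medians of even-length segments average the middle pair.
* Gini `G` is defined 0 when the window mean is 0 (all-zero series);
  normalized channels are nonnegative, so `G` is well defined elsewhere.
* Global importance ties break lexicographically by feature name, making
  reports deterministic.
* FAR with zero alarms, AUROC/recall with a single class, and subtype groups
  with no events are reported `NA`, never silently 0.
* Equal normalization bounds, uncharted signals, unknown configuration keys,
  schema mismatches at predict time, and non-finite features all raise
  immediate errors naming the offender.
* Determinism: every stochastic step (generator, subsampling, shadow
  shuffles, initialization, batching) is seeded from the configuration; with
  a fixed BLAS thread count, refitting reproduces predictions bit for bit.

## Problem sizes in the test suite

The suite exercises the full pipeline at the default study conditions
(400 patients, 4% arrest fraction, three seeds) and scales supporting
experiments to keep a complete run comfortable on a single CPU: the
permutation-null calibration uses an 80-patient cohort with the
gradient-boosted backend (a null is backend-agnostic), oracle-equivalence
checks use hundreds of small randomized instances, and power checks for the
statistical utilities use their specified 100 replicates.

## Known limitations

* The attentive backend is a faithful small-scale rendering of the
  attentive-masking idea, not a line-by-line network reproduction; widths,
  step counts and the optimizer live in configuration.
* Mask attributions are unsigned; direction comes from the group statistics.
* The generator does not model treatment feedback (interventions that
  reverse deterioration), circadian structure, or cross-signal correlation
  beyond the shared pre-arrest ramp.
* MEWS components that need assessments outside the six vitals (mental
  status, urine output) are excluded by construction.
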
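---
title: "Methods: models, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modeling assumptions, the synthetic cohort
generator, the default parameters and the numerical choices behind
`glucolens`. It states no empirical results; every number the package
claims about itself is computed by the test suite or the acceptance
script at run time.

## The problem and the outcome variables

A full-time office worker wears a continuous glucose monitor (CGM,
15-minute cadence) and a thigh-worn activity sensor, receives a
standardized lunch on workdays, and logs meals and work timing. For each
logged lunch the package computes four outcomes over a 3-hour
postprandial window:

* **AUC** — the absolute trapezoidal integral of glucose versus time, in
  mg/dL·h. For a constant 100 mg/dL over 3 h this is 300; it is *not*
  baseline-subtracted, so values track overall glucose exposure.
* **iAUC** — the incremental AUC above the glucose level at meal time
  (linearly interpolated from the bracketing samples), counting only the
  positive part. Segments crossing the baseline are split exactly at the
  crossing, so iAUC is never negative.
* **MaxBGL** — the maximum sampled glucose inside the window.
* **Hyperglycemia label** — 1 when MaxBGL reaches 140 mg/dL
  (inclusive threshold).

Windows are closed on sample timestamps, and any in-window sampling gap
wider than `max_gap_min` (default 45 min, three missed samples) marks
the metric missing rather than silently interpolating across the hole.

Two overnight features accompany the outcomes: *fasting glucose*, the
minimum reading in the closed 6–10 AM window, and *recent CGM*, the mean
reading from midnight (inclusive) to 8 AM (exclusive).

## Feature sets

Five named feature sets share a 15-column core (overnight glucose,
lunch and work-start clock times, work-from-home flag, BMI, day of week,
and the nutrition-facts panel of the lunch scaled to *consumed* amounts
via the logged leftover fraction):

| set            | adds                                   | columns |
|----------------|----------------------------------------|---------|
| `Sensor+GL`    | 6 sensor durations + glycemic load     | 22 |
| `Sensor+Macro` | 6 sensor durations + 4 macronutrients  | 25 |
| `Self+GL`      | self activity score + glycemic load    | 17 |
| `Self+Macro`   | self activity score + 4 macronutrients | 20 |
| `All`          | everything above                       | 27 |

The sensor durations are sitting/standing/stepping seconds over two
windows (midnight→lunch and work-start→lunch), with lying and seated
transport counted as sitting and cycling as stepping; events straddling
a boundary contribute only their in-window portion. The *glycemic load*
of a meal is

```
GL = 19.27 + 0.39·net_carbs − 0.21·fat − 0.01·protein² − 0.01·fiber²
```

with protein and fiber squared and all inputs in consumed grams. The
*self activity score* is `mean(walking %) + 12 · mean(standing %)` over
strictly previous days of the same study phase, so it carries no
same-day information; the first day of each phase has no score and its
row is dropped from the Self/All sets.

BMI has no home in the four time-series sources, so a small
`participants.csv` (id, BMI) acts as the enrollment record.

## The synthetic cohort generator

Real CGM study data of this kind are private, so the package validates
itself on a generator with *known* effect structure. Per participant-day,

```
G(t) = baseline + Σ_meals A_m · r((t − t_m)/τ) + ε,   ε ~ N(0, noise_sd²)
```

floored at a physiologic 40 mg/dL. The response kernel
`r(u) = u·exp(1−u)` rises from 0 to a peak of exactly 1 at `u = 1` and
decays; with `τ = 45` min the excursion peaks 45 minutes after the meal
and has largely decayed within the 3-hour window, and the peak lands
exactly on a 15-minute sample. The lunch amplitude encodes the ground
truth the models must recover:

```
A = max(0, gl_effect·GL − stepping_effect·stepping_min + sitting_effect·sitting_h)
```

Defaults: `gl_effect = 1.6` mg/dL per GL unit, `stepping_effect = 0.25`
mg/dL per pre-lunch stepping minute, `sitting_effect = 4` mg/dL per
at-work sitting hour, baseline 95 ± 8 mg/dL between participants, noise
4 mg/dL. `gl_effect` was calibrated once so that roughly 40% of lunches
cross the 140 mg/dL threshold — a label-prevalence design decision made
against generator output only, never against model results. Unlogged
breakfast and dinner excursions with random small amplitudes are added
so traces are not trivially lunch-only; their amplitudes use the same
`gl_effect`, so a zero-effect parameterization yields a flat baseline
trace.

Activity days are tiled with non-overlapping gamma-length bouts whose
class mix depends on day period and phase (the Stand and Move
intervention phases shift the at-work mix toward standing and stepping,
respectively). Each participant runs Baseline first, then Stand and Move
in random order. Weekends are generated in the CGM and activity streams
but carry no meal or work rows. Self-reported activity percentages are
the true sensor-derived percentages plus truncated Gaussian reporting
error (sd 5 points, clipped at ±12).

What the generator does **not** emulate: meal-to-meal carryover,
circadian baseline drift, sensor dropout and compression artifacts,
dawn-phenomenon dynamics, inter-day autocorrelation beyond the fixed
per-participant baseline, and any real nutrition covariance structure
beyond the macro draws. Conclusions about model *families* on this
cohort transfer to real data only directionally.

## Models

* **Random forest** (`randomForest`), tree count ∈ {10, 50, 100}.
* **Ridge** — closed-form `(XᵀX + αI)⁻¹ Xᵀy` with the intercept
  unpenalized, α ∈ {1, 0.1, 0.01}. The closed form keeps the enumerated
  α values meaningful; path-based implementations rescale the penalty by
  sample size.
* **MLP** — a from-scratch feed-forward network (ReLU, full-batch Adam,
  10% validation split with early stopping, small L2), with 13
  enumerated layer layouts from a single hidden layer up to
  (160, 80, 40, 40, 40, 40, 20, 10). Hand-written because no
  multi-hidden-layer MLP package is available in the target environment;
  nnet is single-layer.
* **Gradient boosting** (`xgboost`), depth 4, learning rate 0.1,
  single-threaded, seeded.

All backbones standardize features with training-only statistics stored
in the fitted object; constant features are dropped with a warning. The
**soft-voting ensemble** averages member class-probability vectors and
breaks exact 0.5 ties toward the positive class. **ADASYN** balancing
synthesizes minority rows along segments toward minority neighbours, in
proportion to the majority share of each row's k-nearest neighbourhood;
**Gaussian augmentation** jitters features by `sigma · sd(feature)`.
Both refuse to run on anything marked as a test row — leakage is a
hard error, not a convention.

## Evaluation designs

Ratio splits take `floor(n · fraction)` training rows; balanced-test
splits hold out exactly `n_per_class` real rows per class; k-fold,
leave-one-subject-out and leave-one-out return fold lists.
Personalization moves one positive and one negative row of the held-out
subject into training; a held-out subject with only one observed class
cannot donate both, and such folds fall back to the unpersonalized
evaluation. Repeated experiments derive per-repetition seeds from one
master seed, so reports are exactly reproducible.

The training-fraction sweep shares repetition seeds across fractions
(common random numbers): within a repetition every fraction sees the
same row permutation, so training sets are nested and per-fraction means
are paired. This is a variance-reduction device for learning-curve
comparisons; it changes no individual experiment's distribution.

NRMSE divides RMSE by the mean of the observed values (0.123 reads as
"within a 12.3% average error margin"); tolerance fractions use strict
inequality. Macro precision/recall/F1 treat a never-predicted class as
zero precision.

## Zero-shot prediction interface

A provider is anything with a `predict_fn(prompt) → character` field.
Prompts serialize the feature row as `name: value` lines into a fixed
template; only the input block varies between rows. The first numeric
token of a response is the prediction; a response with no finite
positive number counts as a refusal, refusals are retried and then
marked failed, and providers that fail on every row are dropped with a
message. Responses are cached per (provider, prompt). The tested
provider is a deterministic mock of tunable skill (linear guess from
parsed features plus prompt-hash-seeded noise); hybrid fusion appends
provider predictions as extra feature columns (`Hybrid` one per
provider, `Hybrid_v2` the designated best provider, `Max` additionally
Gaussian-augments training rows only).

## Explanations

**Counterfactuals** answer "what minimal lunch/activity change flips
this predicted hyperglycemia?". The search perturbs 1–3 mutable features
per candidate in seeded random-restart batches with escalating radius,
clips to observed training ranges, discards candidates that do not flip
the predicted class, and greedily selects k candidates scoring
`(p_target − 0.5) − 0.5·proximity + 1.0·diversity` where distances are
L1 in z-scored units. BMI, day of week and the two overnight glucose
summaries are immutable by default — a counterfactual cannot retro-act
on them. Validity of a returned set is 1 by construction; when nothing
flips within budget the set is returned empty with a diagnostic, never
fabricated. Set metrics: validity, mean pairwise L1 diversity, mean L1
distance to the query, and mean count of changed features.

**Shapley attributions** use marginal contributions along random feature
permutations against sampled background rows. Contributions along each
permutation telescope, so per-row attributions sum *exactly* to
`prediction − mean(background prediction)`; rankings average |value|
across independently seeded trials.

## Numerical and engineering choices

* Timestamps are timezone-naive local clock time stored as UTC POSIXct,
  so arithmetic never crosses daylight-saving transitions; activity
  events serialize with microsecond precision so contiguous tilings
  survive CSV round-trips.
* Trapezoidal integration is exact for the piecewise-linear interpolant;
  the iAUC positive part splits segments at baseline crossings
  analytically. The test suite checks both against a dense-grid
  reference integrator at 10⁻⁹ relative tolerance.
* All stochastic entry points take an explicit seed, run under a local
  RNG scope, and leave the caller's RNG stream untouched; child seeds
  derive from a string hash, so adding a repetition never reshuffles
  earlier ones.
* Day-of-week is encoded 0 = Monday.

## Open questions resolved during implementation

* The 12× multiplier in the self activity score is implemented verbatim
  from its source description, although it reads like a possible typo
  for a percentage weighting.
* The `All` feature table has 27 model inputs under the layout above;
  sources describing a larger count likely include identifiers or
  targets in the tally.
* Whether the reference MLPs used early stopping is unstated; this
  implementation uses a 10% validation split with patience, which makes
  the hand-written optimizer robust across the 13 layouts.
* The counterfactual method's exact hyperparameters are unspecified;
  the proximity/diversity weights above are fixed defaults, and only
  construction-level properties (validity, immutability, range
  clipping) are treated as contracts.

## Limitations

The cohort is synthetic; absolute metric values have no clinical
meaning, and only relative statements (signal recovered, ensemble vs
member, learning-curve shape) are tested. The LLM interface is
exercised with mock providers only. The MLP is a minimal implementation
tuned for hundreds of rows, not thousands. Counterfactual search is
random-restart rather than gradient-based, which is robust for 27
features but would not scale to very wide tables.
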
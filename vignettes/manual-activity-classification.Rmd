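---
title: "Classifying manual activities from wrist- and finger-worn gyroscopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying manual activities from wrist- and finger-worn gyroscopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(manuclass)
```

## The measurement problem

Clinicians assessing hand function rely on questionnaires and supervised
tests; neither observes what a patient's hands actually do at home. Small
inertial measurement units worn where everyday accessories sit — a
wristband and rings on the thumb and index finger of each hand — make a
direct, unobtrusive record possible. `manuclass` implements the analysis
half of that idea: given synchronized triaxial gyroscope streams from the
six sensors and annotations of when each repetition of an activity of
daily living happened, it assigns every repetition to one of five
categories defined by how the hands are used:

1. unimanual;
2. bimanual with a stabilizing hand and finger activity of the active hand;
3. bimanual with a stabilizing hand and global activity of the active hand;
4. bimanual with finger activity of both hands;
5. bimanual with a global activity of both hands.

Categories rather than individual activities are the target because
activities in the same category share a movement pattern, and are
therefore likely to be impaired together in a given pathology: tracking
whether a category of activity reappears during recovery is the clinical
signal of interest.

## The model

All classification rests on two dimensionless ratios computed from the
angular-speed norms of the six gyroscopes over one repetition. For each
sensor the per-sample norm $\sqrt{\omega_x^2+\omega_y^2+\omega_z^2}$ is
averaged over the annotated window (no filtering is applied to the raw
signal). Averaging the norm, rather than taking the norm of the averaged
angular-velocity vector, is deliberate: manual movement is oscillatory,
and a vector average would cancel toward zero instead of measuring
activity magnitude. The *hand signal* is the mean of a hand's three
sensors, and the *fingers signal* the mean of its thumb and index
sensors. With synchronized, uniformly sampled streams, averaging the
per-sensor means and averaging the aggregated norm series coincide; the
test suite asserts this equivalence rather than leaving it implicit.

The **hands ratio** compares the two hands:

$$\mathrm{HR} = \frac{\text{most active hand}}{\text{least active hand}} \ge 1 .$$

HR near 1 means both hands contribute equally; it grows when one hand
stabilizes and explodes when one hand rests.

The **fingers-to-wrist ratio** measures finger independence within a hand:

$$\mathrm{FWR} = \frac{\text{fingers' mean angular speed}}{\text{wrist mean angular speed}} .$$

FWR near 1 means the hand moves as a whole (tool manipulation); values
around 2 and above indicate fingers moving independently of the wrist
(writing, typing, buttoning). Two variants are always computed and
carried: `fwr_active`, the FWR of the most active hand, and `fwr_mean`,
the average of the two hands' FWRs. At inference time the dominant hand is
unknown, so the most active hand — the larger hand-signal mean — is the
label-free proxy used for stabilizing-hand activities; for activities with
both hands engaged the two hands are averaged. Ties in hand activity are
broken toward the right hand, a probability-zero event on real signals
that must nevertheless be deterministic.

### The decision tree

Classification proceeds in three steps over learned cutoffs
$(c_1, c_2, c_3, c_4)$:

1. $\mathrm{HR} > c_1$: unimanual — stop.
2. $\mathrm{HR} > c_2$: stabilizing-hand branch; otherwise both-hands
   branch. $c_2 < c_1$ always, because a stabilizing hand still performs
   low-amplitude movements.
3. Stabilizing branch: $\mathrm{FWR}_{\text{active}} > c_3$ separates
   finger activity from global hand movement; both-hands branch:
   $\mathrm{FWR}_{\text{mean}} > c_4$ does the same.

All inequalities are strict, with equality falling to the lower branch;
the convention is arbitrary (exact ties have probability zero) but fixed
for determinism. `Inf` feature values, produced when a denominator falls
below $\varepsilon = 10^{-9}$ °/s, compare greater than any finite cutoff
and so route a repetition with a truly still hand to `unimanual`.

### Learning the cutoffs

Each cutoff is learned by a ROC analysis on a nested subset of labeled
repetitions: (A) all repetitions, HR, positive class unimanual; (B)
bimanual repetitions, HR, positive class stabilizing-hand; (C)
stabilizing-hand repetitions, `fwr_active`; (D) both-hands repetitions,
`fwr_mean`. The optimal cutoff jointly maximizes sensitivity and
specificity — operationalized as the maximum of Youden's
$J = \text{sens} + \text{spec} - 1$, which at equal class weights
minimizes total misclassifications. Ties in $J$ are broken toward the
larger threshold (the more specific rule).

Candidate thresholds are, by default, midpoints between adjacent distinct
scores, bracketed by $\pm\infty$ sentinels; an `observed` convention
(thresholds at the scores themselves) is available because published
cutoff values cannot disambiguate which convention produced them, and the
two differ only in where inside an indifference interval the threshold is
placed, never in the achieved error counts. A midpoint with an infinite
neighbour is replaced by the finite score plus one: every threshold in
that open interval yields identical rates, so the choice only affects the
reported number. ROC rates are computed by exact counting, and the
trapezoidal AUC then equals the Mann–Whitney pairwise probability with
ties counted one half — an identity the test suite checks against an
$O(n^2)$ oracle and against an independent ROC implementation (pROC).

### Two accounting views of accuracy

Validation is leave-one-subject-out: each participant is held out in
turn, cutoffs are learned on the remaining participants, and the held-out
repetitions are scored. The primary accounting checks, per repetition,
whether each feature lies in the range its *true* category requires at
each applicable step (unimanual repetitions face only step 1); a
repetition is overall-correct when every applicable criterion passes.
This per-criterion view can differ from plain hierarchical routing for
mis-branched repetitions — a repetition that fails step 1 may still pass
its true category's later criteria — so the 5×5 confusion matrix of tree
predictions is reported alongside. Per-activity and per-category
accuracies pool repetitions across folds; pooling (rather than averaging
per-activity percentages) weights every repetition equally, and the
alternative would differ only when activities contribute unequal
repetition counts.

The bundled worked example (`example_features()`, `example_cutoffs()`)
exercises this accounting on one held-out participant's printed feature
table. One anomaly in that source table is worth recording: the
"Writing a sentence" repetition 4 row prints different HR values in its
step-1 and step-2 columns (20.13 vs 27.54), although a repetition has a
single HR. The bundled table stores the step-1 value; the package computes
one HR per repetition and does not reproduce the inconsistency.

## The synthetic generator

The package must be testable without any recorded cohort, so the
`synth` module generates six-sensor datasets whose *feature-level*
structure is controlled exactly. Per-repetition targets (HR, per-hand
FWR, active-hand wrist speed) are drawn from per-category ranges;
per-sensor target means follow from the hand-signal algebra; and each
sensor's series is synthesized as a random burst in the norm domain,
distributed isotropically over x/y/z and rescaled so the empirical
time-averaged norm equals its target to floating-point accuracy. Because
the pipeline consumes only norms, realism in the axis decomposition is
secondary, and exact rescaling makes tests sharp: empirical HR and FWR
equal their drawn targets.

Default ranges under the `well_separated` preset — HR uniform on
[30, 90] (unimanual), [6, 18] (stabilizing), [1, 3] (both hands); FWR on
[2.6, 6] (finger branches) and [1.2, 2.1] (global branches) — are chosen
to bracket the feature values observed for the corresponding categories
in practice while leaving clean inter-class gaps, so any correctly
learned cutoff must land inside a gap and pipeline recovery can be held
to a ≥ 95% standard. Subject-level variation is multiplicative lognormal
(sigma 0.2 on speeds, which cancel in the ratios; 0 on ratios under this
preset). The `realistic` preset widens the ranges until neighbouring
categories overlap (e.g. stabilizing HR down to 3.5, both-hands HR up to
5.5) and adds ratio noise at the subject (sigma 0.12) and repetition
(sigma 0.10) levels, yielding imperfect, subject-dependent accuracy in
the high-80s-percent regime; because that figure depends entirely on the
preset, it is illustrative and never a pass/fail criterion.

What the generator does *not* emulate: activity onset/offset detection
(windows are given), non-stationarity within a repetition, sensor
placement error, axis-level biomechanics, or accelerometer channels.
Passing tests therefore demonstrate that the feature extraction, cutoff
learning and validation machinery are correct, not that the published
accuracy generalizes to new cohorts — that requires real recordings,
which `evaluate_external_dataset()` accepts in the documented CSV
dialect.

## Numerical and design choices

* **Sample rate.** Generated test data default to 100 Hz; the ratios are
  rate-independent in expectation, and 100 Hz keeps generated datasets
  small. The targeted hardware records at 500 Hz, and the rate is a
  parameter throughout.
* **Problem sizes.** Tests and the cross-validation examples use 6
  synthetic subjects × 5 categories × 5 repetitions (150 repetitions,
  matching a realistic single-site study) with repetitions of 3–6 s; the
  full pipeline on that size runs in about a second.
* **Half-open windows** `[t_start, t_end)` make consecutive repetitions
  concatenate without double-counting samples; a sample exactly at
  `t_end` belongs to the next window.
* **Timestamp validation.** Files declare a rate and carry explicit
  timestamps, validated strictly increasing and uniform to a relative
  tolerance of 1e-6 per interval — tight enough to catch corrupt or
  truncated files, loose enough for decimal-rounded CSV timestamps.
* **Calibration** is a linear per-axis model `raw = value/gain + offset`
  fit by ordinary least squares, applied as
  `value = (raw − offset) × gain`; it is optional at read time since
  recordings may already be in physical units.
* **Degenerate inputs.** Single-class ROC labels, empty segment windows,
  all-equal scores, missing categories in a training fold, and
  zero-denominator features all raise informative errors or documented
  sentinels rather than propagating NaN.

## Limitations

The classifier assumes annotated repetition windows; detecting activity
onset and offset is out of scope. It uses gyroscopes only — accelerometer
channels are read and stored but contribute no feature. Cutoffs learned
on one cohort transfer only as well as the cohort represents the target
population; borderline activities (handwriting with a barely-moving
stabilizing hand is the canonical case) sit near the step-1 boundary and
dominate the error budget of the per-criterion accounting.
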
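---
title: "Classifying giraffe behavior from head-mounted accelerometers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying giraffe behavior from head-mounted accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Giraffes are hard to observe in the wild, but their behavior can be inferred
remotely from triaxial accelerometers mounted on the head: each behavior
leaves a characteristic combination of head posture (the static gravity
projection on the three body axes) and movement (oscillation, variance)
in the acceleration record. `ethoacc` implements a complete pipeline for
this inference task:

1. ingest recordings from two logger designs and map them onto common
   semantic axes — sway (lateral), surge (anterior–posterior), heave
   (dorso-ventral);
2. label recording windows from an observers' ethogram and keep only
   pure-behavior windows;
3. harmonize individuals onto a common orientation reference;
4. extract a fixed per-window predictor set;
5. classify with Random Forests under two validation designs; and
6. report per-category one-vs-rest accuracy, precision and recall.

Because real deployments are expensive, the package ships a seeded
synthetic-data generator that emulates labeled behavior streams through both
device models, so the entire pipeline is testable end to end.

## Device models

Two logger designs are built in:

* **Burst logger** (`burst_device()`): bursts of 2.43 s sampled at 33.8 Hz —
  exactly 82 samples per axis — every 20 s; values are unit-free digital
  numbers in 0..4095; the raw x axis measures heave, y sway, z surge.
* **Continuous logger** (`continuous_device()`): one sample per second
  (its "heartbeat"), signed counts in −32000..+32000, transmitted live and
  therefore prone to gaps; raw x measures surge, y sway, z heave.

The axis maps are bijections applied as pure permutations; parsing never
transforms a sample value. Out-of-range values on ingest are hard errors —
a real export can never exceed its encoding, so such a value indicates file
corruption, and silent clipping would bias moments. (Clipping is legitimate
only inside the simulator, where the physical signal genuinely can exceed
the encoding range.)

On-disk dialects are deliberately minimal CSV: a long-form burst file
(`tag_id,individual,burst_start_iso8601,axis,sample_index,value`), a
continuous file (`timestamp_iso8601,x,y,z` plus optional vendor columns),
and the ethogram (`individual,start_iso8601,end_iso8601,behavior_code`).
Vendor-provided pitch/roll columns in continuous exports are ignored:
orientation features are always recomputed so both devices share one
definition. Timestamps are UTC seconds internally and ISO-8601 with
millisecond precision on disk.

## Labeling and filtering

An ethogram is a set of non-overlapping timed behavior intervals per
individual. Interval containment is **half-open** `[start, end)` with no
tolerance slack: the observation protocol is synchronized to the second, and
an explicit convention avoids boundary disputes. A burst whose samples all
fall in one interval takes that behavior; a fully observed burst spanning
two or more behaviors is `mixed`; a burst touching unobserved time is
`unlabeled` (unlabeled takes precedence over mixed when both apply). Only
pure-behavior bursts enter the analysis.

The continuous stream is segmented into variable-length behavior sections:
maximal runs of consecutive 1 Hz samples inside a single interval, split by
transmission gaps. Sections shorter than 5 samples are discarded before
feature extraction — standard deviation, skewness and kurtosis need at
least 3–4 points, and 5 adds margin.

To avoid bias from unequal behavior frequencies, a balanced subsample of 30
bursts per individual and category is drawn without replacement; categories
with fewer than 30 available bursts are dropped entirely and reported. The
draw is seeded and recorded in the dataset's provenance.

## Calibration

Re-attaching a device shifts its orientation slightly, moving every axis by
an approximately constant offset. Because values vary little while an animal
stands without any movement, the per-axis mean over annotated quiet-standing
bursts (ethogram code `STA_STILL`) serves as each individual's reference;
`harmonize()` adds the per-axis difference to a chosen reference individual
to all of an individual's samples. The reference is explicit and
configurable rather than hard-coded to one animal. Design notes:

* stillness must be annotated by the observer, never inferred from the
  signal — signal-based stillness detection would be a new, unvalidated
  inference step;
* corrected values may leave the integer encoding range and are kept as real
  numbers, not re-clipped;
* the correction is purely additive, so sd, skewness, kurtosis and the
  spectral weighted mean are untouched, and harmonizing twice is the
  identity.

## The predictor set

Per burst: per-axis arithmetic mean (`mn_*`), sample standard deviation with
n−1 denominator (`sd_*`), inverse coefficient of variation
(`icv_* = mean/sd`), spectral weighted mean frequency (`wm_*`, burst mode
only), excess kurtosis (`kurt_*`) and skewness (`skew_*`), plus three
combined features: `q`, `pitch`, `roll` — 21 predictors for fixed-length
bursts, 18 for variable-length continuous sections (`wm` depends on the
window length, so it is meaningless across sections of different lengths).

Numerical conventions, chosen where the construction is genuinely open and
documented so they are auditable:

* **ICV** is mean/sd, the reciprocal of the coefficient of variation. A
  zero-variance burst would give ±∞; instead the sentinel `sign(mean)·1e9`
  is emitted so tree models keep working. Skewness and kurtosis of a
  constant burst are reported as 0.
* **Skewness/kurtosis** use plain moment estimators without small-sample
  bias correction; kurtosis is excess (Gaussian → 0).
* **`wm`** is computed on the mean-removed signal over positive-frequency
  bins `k = 1..floor(n/2)` of the discrete Fourier transform, weighting by
  spectral *magnitude* (not power), DC excluded — with DC included the
  statistic would merely duplicate the per-axis mean. A constant burst has
  an all-zero spectrum and returns the sentinel 0, outside the valid open
  interval (0, Nyquist]. With a rectangular window, leakage biases `wm`
  toward mid-band for tones far from a bin center; a 4 Hz tone at the burst
  logger's 82-point window still lands within one bin width (0.41 Hz) of
  the truth, and bin-centered tones are recovered exactly.
* **`q`** is the burst mean of the per-sample Euclidean norm
  `sqrt(sway² + surge² + heave²)` — not the norm of the per-axis means; the
  two are related by Jensen's inequality (`q ≥` the norm of means), which
  the tests assert so any accidental switch is detectable.
* **Pitch and roll** follow the static-gravity convention
  `pitch = atan2(−mean(surge), sqrt(mean(sway)² + mean(heave)²))`,
  `roll = atan2(mean(sway), mean(heave))`, in radians. Raw counts are
  unit-free, so the device's zero-g count (2048 for the burst logger, 0 for
  the continuous one; a `device_spec` field, hence configurable) is
  subtracted before computing `q`, pitch and roll; the affine scale cancels
  in the angles.

## Classification and validation

The classifier is a Random Forest (CRAN package `randomForest`): an
ensemble of decision trees whose prediction is the plurality vote. Defaults
are 500 trees and `mtry = floor(sqrt(p))` — that package's classification
defaults — with no depth limit. Sentinel feature values are passed through
as ordinary numbers; trees split on them naturally, so no imputation
machinery is needed.

Two validation designs:

* **Leave-one-burst-out** (`leave_one_out()`): N folds; fold i trains on the
  other N−1 rows and predicts row i. Rows are processed in `burst_id` order
  and fold i is seeded with `base_seed + i`, so predictions are reproducible
  and invariant to row order. This design measures how well an individual's
  own repertoire can be recognized.
* **Leave-one-individual-out** (`cross_individual()`): train on the pooled
  bursts of all other animals, predict every burst of the withheld one —
  the deployment-relevant generalization test. Test categories absent from
  training are flagged `untrainable`; the model cannot emit them.

Structurally, test rows never enter training in either design, and the
tests assert coverage (each burst predicted exactly once).

## Metrics

Per category, one-vs-rest tallies over the full prediction set:
`TP = cm[c,c]`, `FP` and `FN` the off-diagonal column and row sums, `TN`
the rest. Then

* accuracy = (TP + TN) / (TP + TN + FP + FN),
* precision = TP / (TP + FP),
* recall = TP / (TP + FN).

Note the true negatives inside "accuracy": this is the one-vs-rest
proportion of all predictions classified correctly, positively or
negatively — deliberately not the global multiclass accuracy many libraries
report under that name. Overall metrics are unweighted arithmetic means over
categories with defined values; zero-denominator ratios are `NA` and
excluded, as are categories dropped by the n < 30 rule.

Device comparison uses the classical paired t-test on per-category accuracy
differences (`stats::t.test(paired = TRUE)`), df = pairs − 1. The two-sided
p-value is the default report and the one-sided value ("device 1 better")
is also emitted, since either tail can be of interest. An exactly constant
difference vector has zero standard error; the statistic is reported as 0
(all differences zero, p = 1) or ±∞ (constant nonzero difference, p = 0)
instead of erroring.

## The synthetic generator

`generate_truth()` draws behavior bouts as a renewal process — codes from a
uniform Markov chain excluding self-transitions, bout durations exponential
with per-behavior mean dwell — and the signal within a bout is

    static_g  +  Σ sinusoids  +  Gaussian noise     (per semantic axis, in g)

plus an optional per-individual constant attachment offset.
`render_device()` samples this through either device model: burst windows
or 1 Hz heartbeat, affine g→count mapping (2048 + 512·g for the burst
logger, 8192·g for the continuous one — any fixed documented affine works
because the values are unit-free; these place ±2 g inside each encoding
range), integer quantization, clipping, and seeded random or interval
dropouts for the continuous device. Everything derives from one scenario
seed and is bit-reproducible.

The default signature set covers the eight behavior categories analyzable
on both devices — standing (STA), feeding above eye level (FEA), at eye-to-
middle (FTM), deep (FED) and ground level (FEG), rumination (RUM), drinking
(DRI) and walking (WAL) — plus the `STA_STILL` calibration reference.
Static projections encode head height (head-up behaviors load heave,
head-down behaviors surge); chewing and gait oscillations sit at
0.9–2.4 Hz. The static vectors are mutually separated by at least three
noise standard deviations (minimum pairwise gap 0.2 g at noise sd 0.05 g),
with the posture-similar pairs (RUM↔FTM, DRI↔FEG) kept closest — the
confusion structure a head-mounted sensor actually faces. Bout dwell means
(40–150 s) and the 8 h session length give every category comfortably more
than 30 pure bursts per animal on both devices.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: within-category postural variety (a real STA bout
mixes still standing and scanning), inter-individual movement-style
differences beyond additive offsets, non-stationary noise, sensor drift,
gait harmonics and transients. On this generator the classes are separable
by construction, so the pipeline reaches near-perfect accuracy; that
validates the machinery (no leakage, correct features, working calibration),
not any claim about field performance, where published head-mounted studies
report overall accuracies in the low-to-mid 90s. Conversely, making two
signatures identical collapses their pairwise recall toward the 50% chance
level while distinct categories stay high — the degradation direction the
tests assert.

## Problem sizes and reproducibility

The shipped analyses and the acceptance script use: 3 individuals, 8 h
sessions, 30 bursts per category and animal, 500 trees. These sizes are the
package's own defaults, chosen so that every category clears the n = 30
rule with margin while a full leave-one-out run on one animal (240 fits)
completes in well under a minute on a laptop core. All randomness is
seeded: scenario, subsample and classifier seeds are recorded in a
provenance manifest, and rerunning an identical configuration reproduces
identical outputs.

## A worked run

```{r example}
library(ethoacc)

cfg <- scenario_config(seed = 1)
res <- run_pipeline(cfg, devices = list(burst_device()),
                    designs = c("loo", "cross_individual"))
res$burst_logger$loo$giraffe1$report
sapply(res$burst_logger$cross, function(x) x$report$overall)
```

The numbered scripts under `analysis/` run the same stages as a narrative
workflow — `01_simulate.R` writes device exports and the ethogram,
`02_individual_loo.R` and `03_cross_individual.R` run the two validation
designs, `04_device_comparison.R` the paired device test — with tables
under `results/`.

## Known limitations

* The synthetic scenario is the only bundled data source; conclusions about
  real giraffes require real labeled recordings.
* The continuous device's `wm` exclusion means its feature space is a
  strict subset; no attempt is made to re-weight or window sections to
  recover spectral features.
* Calibration is additive per axis; a genuinely rotated attachment would
  need a rotation-matrix correction, which is out of scope.
* Random-Forest hyperparameters beyond trees/mtry (class weights, depth)
  are fixed at package defaults.
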
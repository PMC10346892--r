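---
title: "Methods: light-weight activity recognition from lower-limb wearables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: light-weight activity recognition from lower-limb wearables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gaitrec` implements a deliberately small pipeline for recognising seven
activities of daily living (sitting, standing, level walking, ramp
ascent/descent, stair ascent/descent) from 19-channel lower-limb wearable
recordings sampled at 500 Hz. This vignette explains the model and the
design choices behind the implementation; the README shows a worked
example.

## The data model

The unit of data is the *motion circuit*: one continuous recording of one
subject traversing a fixed activity script, with a per-sample activity
label. Even-numbered circuits run sitting → standing → walking → ramp
ascent → walking → stair descent → walking → standing → sitting;
odd-numbered circuits run the reverse variant with stair ascent and ramp
descent. Circuits — never individual windows — are the unit of data
splitting, so no recording contributes to both training and evaluation.

The 19 channels are waist accelerometer x/y and waist gyroscope x;
accelerometer x/z and gyroscope y on each thigh and shank; and four
goniometer (joint-angle) channels, both knees and both ankles. Left and
right sides are distinct channels throughout; no mirroring or pooling is
applied. Named subsets (`imu_only`, 15 channels; `gonio_only`, 4) support
sensor-ablation experiments.

## Preprocessing

**Transition removal.** Labels around an activity switch are unreliable —
the body is mid-transition. 500 samples (1 s) centred on every label
change are removed, split 250/250 across the boundary. The split is a
package choice (symmetric placement is the natural default when only the
total width is specified). Runs left shorter than one window are dropped.

**Windowing.** Each single-activity run is tiled into non-overlapping
25-sample windows (0.05 s); the tiling is repeated five times, shifted by
5 samples each pass. The union of the five passes is exactly the set of
stride-5 sliding windows, so no window is duplicated; the pass structure
is kept because temporal context (below) is built *within* a pass, making
consecutive context windows 25 samples apart.

**Features.** Nine time-domain statistics per window per channel: mean,
median, population standard deviation (divide by W, not W−1), min, max,
initial value, final value, MAV and WL. Two conventions deserve note:

* *MAV* here is the mean absolute deviation from the window mean,
  (1/W) Σ |xₙ − μ| — not the mean absolute signal value.
* *Median* defaults to the true sorted median (the ⌈W/2⌉-th order
  statistic; the 13th-smallest of 25). A strict-formula mode
  (`median_mode = "center"`) returns the raw centre sample instead, for
  users who want the window's literal midpoint reading; the sorted median
  is the default because the feature is a median, and the centre sample is
  already nearly captured by the initial/final-value features.
* *Min/max* are the extreme values, not their positions.

**Context stacking.** The feature vectors of three consecutive windows
(same circuit, same run, same pass) are concatenated into one 513-long
input, labelled by the newest window. The first two windows of every
(run, pass) group yield no row. Cross-pass stacking was considered and
rejected: windows from different passes interleave at 5-sample offsets
and would make the effective context span configuration-dependent.

**Scaling and balancing.** Feature columns are z-scored with statistics
fitted on the training split only; zero-variance columns are centred and
passed through (scale floored to 1). Classes are balanced by downsampling
to the rarest class — gait windows are highly repetitive, so discarded
majority rows are largely redundant. Balancing is applied to the
*training* split only; evaluation splits stay unbalanced so reported
accuracy reflects the raw label distribution. A `balance_all` switch
balances every split for users who prefer balanced evaluation marginals.
`balance_classes()` also accepts a per-class cap (`n_per_class`), a
problem-size dial used by the shipped end-to-end runs (below).

## The classifier

A single-hidden-layer network: D = 513 inputs, H = 100 tanh hidden units,
K = 7 *independent sigmoid* outputs. The outputs are deliberately not a
softmax: each unit is a one-vs-rest detector and the loss is summed binary
cross-entropy,

J = −(1/N) Σₙ Σₖ [ yₙₖ log ŷₙₖ + (1−yₙₖ) log(1−ŷₙₖ) ] + (λ/2N) Σ w²,

with biases excluded from the penalty (standard practice) and λ = 2 by
default. The 1/N normalisation keeps λ meaningful across dataset sizes.
Prediction takes the argmax over the K outputs, ties broken toward the
lowest class index. Activations are clipped to [1e−12, 1 − 1e−12] before
the logarithms.

**Training** is full-batch Polack–Ribière nonlinear conjugate gradients.
Each line search must satisfy the strong Wolfe conditions — sufficient
decrease (c₁ = 0.01) and curvature (c₂ = 0.5) — and finds its step by
quadratic/cubic interpolation and cubic extrapolation within classical
limits (interpolation guard 0.1, extrapolation ×3, at most 20 evaluations
per search, slope-ratio cap 100). On a failed search the optimiser
restarts along steepest descent; two consecutive failures end training.
The cost trace over accepted iterations is non-increasing by
construction, and the trace records whether each accepted step met both
Wolfe inequalities. "Epochs" are accepted full-batch iterations (the
default cap is 1000); there is no minibatching. Weights initialise
uniformly in ±√6/√(fan_in+fan_out), seeded.

Gradients are analytic backpropagation, verified in the test suite
against central finite differences at step 1e−5 (relative error < 1e−6).

## Evaluation protocol

Leave-one-subject-out over 8 subjects: per fold, the held-out subject
contributes 4 test circuits; each seen subject contributes 2 validation
circuits (seeded draw) and up to 8 training circuits — 56/14/4 circuits
per fold. Which circuits go to validation/test is a seeded random draw,
exposed so runs are reproducible. Fold metrics are averaged unweighted
across folds. Per-class F1 is TP / (TP + ½(FP + FN)); a class absent from
both truth and prediction scores 0 and is flagged, keeping macro averages
conservative. Nothing from the held-out subject reaches the scaler, the
balancing draw or the weights — the test suite verifies that permuting
the held-out subject's raw samples leaves the trained weights bitwise
unchanged.

Timing (per-row preprocessing and single-row inference) is measured and
reported for information only; it is entirely host-dependent and never
compared against fixed numbers.

## The synthetic generator

Real benchmark recordings are an optional input; the shipped generator
produces circuits with the statistical structure the classifier relies
on, not a biomechanical simulation. Per (activity, channel), a pinned
profile table (`inst/extdata/activity_profiles.csv`) gives a baseline
offset, fundamental amplitude, gait frequency (0 for sitting/standing),
second-harmonic ratio and noise SD; a segment's signal is
offset + A·sin(2πft + φ) + A·h·sin(4πft + 2φ) + Gaussian noise, with one
phase φ per segment (right-side channels lag by π). Segment durations are
uniform on 4–10 s. Subjects differ by a log-normal amplitude scale
(σ = 0.15), a log-normal gait-frequency scale (σ = 0.03) and additive
per-channel offset shifts (σ = 0.15 signal units) — magnitudes in the
range of inter-subject gait variability and sensor-placement differences.
This family was chosen as the simplest whose window statistics (mean, SD,
MAV, WL) separate activities the way gait signals do.

Two deliberate structural properties:

* **Goniometer ambiguity.** The goniometer profiles are identical within
  the ramp-ascent/descent pair and within the stair pair: joint-angle
  excursions alone do not reveal climbing direction, while the
  forward-tilt accelerometer offsets do. The goniometer-only ablation is
  therefore strictly harder by construction, mirroring the qualitative
  ordering seen with real sensor subsets.
* **Subject effects drive the generalisation gap.** Offset shifts move
  unseen subjects' feature distributions away from the training scaler's,
  so unseen-subject test accuracy falls below seen-subject validation
  accuracy, and falls further as the spreads grow — a property the test
  suite checks over three spread levels.

What the generator does *not* emulate: realistic transition kinematics
(segments switch abruptly; the transition-removal step discards the
boundaries anyway), non-stationarity within a segment, correlated
inter-channel noise, and sensor artefacts. Passing tests on synthetic
data therefore demonstrate the pipeline's mechanics and its qualitative
orderings (seen > unseen; all channels > goniometers only), not absolute
accuracies on any real recording.

## Problem sizes in the shipped runs

The default synthetic benchmark (8 subjects × 10 circuits, 4–10 s
segments at 500 Hz) yields ≈2.5 M samples and ≈470 k stacked rows. The
end-to-end runs shipped with the package (acceptance script and
full-pipeline test) train each fold on a balanced subsample of 800 rows
per class with 100 conjugate-gradient iterations — a per-class cap and
iteration budget chosen so the complete 8-fold experiment is comfortable
on a single CPU while leaving validation accuracy far above the 95%
mark it is checked against. The unit-test suite uses much smaller
generator configurations (shorter segments, fewer subjects) for the same
reason; the generator's *defaults* are never changed by tests.

## Known limitations

* Windows are strictly single-activity; the method does not label
  transition periods at all.
* Independent sigmoid outputs can, in principle, produce low confidence
  for every class; argmax still yields a label, but the activations are
  not calibrated probabilities.
* The conjugate-gradient trainer is full-batch: memory and per-iteration
  cost grow linearly with the training set, which is why the per-class
  cap exists.
* Fold construction assumes every subject has enough circuits for the
  requested validation/test draws and errors otherwise.
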
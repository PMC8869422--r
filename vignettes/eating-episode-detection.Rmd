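---
title: "Detecting eating episodes from wrist motion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting eating episodes from wrist motion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eatseg)
```

## The problem and the approach

Eating is built from hand-to-mouth ingestion gestures (bites) that last a few
seconds, interleaved with food preparation and rest. Bottom-up detectors look
for individual bites in ~5 s windows and cluster the detections into meals;
they are blind to everything that happens *between* bites and are easily
fooled by bite-like gestures elsewhere in the day. `eatseg` implements the
top-down alternative: classify a *large* window of raw wrist motion
(0.5–15 minutes of 6-axis IMU data — 3-axis accelerometer plus 3-axis
gyroscope at 15 Hz) as eating vs. non-eating, so that the inter-gesture
context inside a meal is part of the signal. The window classifier is slid
across a full day to produce a per-datum probability of eating `p(e)`, a
two-threshold hysteresis detector converts `p(e)` into episodes, and the
episodes are scored against self-reported meal boundaries.

The pipeline stages map onto the package like this:

| stage | functions |
|---|---|
| I/O (flat-binary days, meal CSVs) | `read_cad_recording()`, `read_episode_list()` |
| preprocessing | `gaussian_smooth()`, `znorm()`, `preprocess_recording()` |
| window cutting / balancing | `cut_training_windows()`, `balance_undersample()` |
| window classifier | `build_model()`, `train_model()`, `predict_windows()` |
| day-scale inference | `sliding_probability()` |
| episode detection | `detect_episodes()` (hysteresis + merge + drop) |
| evaluation | `match_episodes()`, `episode_metrics()`, `boundary_errors()`, `datum_metrics()` |
| experiments | `split_subjects()`, `run_fold()`, `run_crossval()`, `sweep_hyperparam()` |
| synthetic data | `synth_params()`, `generate_day()`, `generate_dataset()` |

## Preprocessing

Each of the six axes is smoothed independently with a Gaussian filter of
σ = 10 samples (two thirds of a second at 15 Hz) and then z-normalized.
Two choices here are ours and are stated as constants rather than options
left implicit:

* the kernel is truncated at 4σ and edges are handled by mirror reflection —
  standard, minimal-edge-artifact choices;
* z-normalization uses the population (1/n) standard deviation and is
  computed **per recording, per axis**. Normalizing each day against itself
  makes days comparable regardless of sensor gain, at the cost of letting an
  unusually active day shrink its own meals slightly. A pooled
  (`stats_scope = "dataset"`) variant is available in
  `preprocess_dataset()` for workflows that prefer global statistics.

A zero-variance axis is a dead sensor; `znorm()` refuses it loudly rather
than emitting NaNs.

## The window classifier

`build_model()` constructs a deliberately small 1D CNN:

* three valid (unpadded) convolution layers, 10 filters each, kernel lengths
  44 / 20 / 4 samples, all with stride 2 and relu activations. 44 samples is
  roughly 3 s of data — one bite;
* global average pooling across time, so a window of *any* length collapses
  to 10 numbers and the parameter count is independent of the window size;
* a 200-unit relu dense layer and a single sigmoid output.

That is 7471 trainable weights:
`(6·44+1)·10 + (10·20+1)·10 + (10·4+1)·10 + (10+1)·200 + 201`.
The forward and backward passes are implemented in this package (im2col +
BLAS GEMM in `src/conv.cpp`, Adam and the training loop in R); a
finite-difference gradient check in the test suite pins the backward pass to
the forward pass at 1e-5 tolerance.

Training uses binary cross-entropy, Adam at learning rate 1e-4, batch size
32, and a fixed number of epochs (default 150) with no early stopping — the
weights after the last epoch are the model. Three details are not fixed by
the architecture description and are our documented defaults, not claims
about any original implementation: the L1 penalty on conv kernels is 1e-4
(small enough that cross-entropy dominates on balanced batches), padding is
"valid", and weights are Glorot-uniform initialized from a caller-supplied
seed. With valid padding and stride 2, the smallest admissible window is 94
samples (~6.3 s); `build_model()` reports this minimum when violated.

Windows are labeled eating when meals cover **strictly more than half** of
the window; overlap is computed against the union of meals, so a window
straddling two snacks counts their combined coverage. Training windows are
cut with a 15 s slide, and the heavy class imbalance (roughly 5% eating in
free-living data and in our synthetic days) is handled by undersampling the
non-eating class to parity — uniformly, without replacement, seeded.
Oversampling is deliberately not offered.

## Day-scale inference

`sliding_probability()` assigns the classifier output for each window to the
window's **center** datum. Two implementation decisions:

* within half a window of the day's edges no full window exists; those data
  get `p(e) = 0`, the conservative non-eating value, so a day's trace is
  total. Meals clipped by the recording boundary are the only thing this can
  hurt, and they are rare;
* the default evaluation stride is 1 datum, but a coarser stride (e.g. 15 =
  one second) with linear interpolation between evaluated centers is
  provided. On smooth traces the difference is well under the hysteresis
  thresholds' resolution (the test suite bounds it at 0.05).

Rather than re-running the CNN on each of ~800k overlapping windows, the
conv stack is evaluated once over the whole day with dilated kernels
(dilations 1, 2, 4 mirror the three stride-2 layers), after which the
window starting at datum *s* pools the layer-3 feature rows
*s*, *s*+8, *s*+16, …. This is algebraically identical to per-window
evaluation — a property asserted, to 1e-12, in the tests — and roughly two
orders of magnitude faster.

## Hysteresis detection

`detect_episodes()` runs a two-state scan: a segment **opens** at the first
datum with `p > TS` and **closes** at the first datum with `p < TE`
(`TE ≤ TS`; defaults 0.8 / 0.4). Both comparisons are strict, matching the
"rises higher than" / "drops to less than" reading; values between the
thresholds preserve the current state, which is what suppresses chatter
around a single threshold. A segment still open at the end of the day is
closed after the last datum (the day simply ended; the evidence for eating
did not).

Post-processing then (1) merges segments whose gap is **at most** 60 s
("within one minute" read inclusively) and (2) removes segments **strictly
shorter** than 60 s — in that order, so two 40 s fragments 30 s apart
survive as one 110 s episode. Real meals are all at least a minute long, so
the removal only discards noise.

## Evaluation

Episode level (unit: one meal): a meal with *any* overlap with a detection
is a true positive, a meal with none is a miss, and a detection overlapping
no meal is a false positive. One detection covering *k* meals contributes
*k* TPs and no FP; a meal fragmented over *k* detections is still one TP.
Touching endpoints (`[a,b)` then `[b,c)`) do not overlap. True negatives are
undefined at this level, so the summary statistics are TPR, FP/TP and
FP/day. With zero TPs, FP/TP is reported as a flagged `NA`, never an
exception — threshold sweeps must keep running through degenerate corners.

Boundary level (unit: minutes, TP meals only): start error is the start of
the *first* overlapping detection minus the meal start; end error uses the
*last* overlapping detection's end. Negative start error means the detector
fired early.

Datum level: standard confusion-matrix ratios over per-datum masks, with F1
and a weighted accuracy `ACC_W`. We define `ACC_W` as balanced accuracy,
`(recall + TNR)/2`; with the datum rates this work is compared on
(recall 0.69, TNR 0.93) it gives 0.81, consistent within rounding with the
published comparison row, but the definition is our documented choice since
the metric's formula is not spelled out where it is reported.

## Cross-validation and sweeps

`split_subjects()` deals subjects (not days) into k folds round-robin after
a seeded shuffle, so fold sizes differ by at most one and no person
contributes to both training and testing; `run_fold()` re-asserts this at
run time and refuses to train otherwise. Repeat days of one subject share
the subject id and therefore a fold. Window accuracy on the held-out fold is
computed on a class-balanced window set, so 0.5 is chance.

`sweep_hyperparam()` tunes one hyperparameter at a time. Threshold sweeps
(TS, TE) reuse the trained fold models and their cached day traces —
re-thresholding a trace is cheap, and the CNN does not depend on TS/TE —
while a window-length sweep necessarily retrains per value.

## The synthetic data generator

`generate_day()` emulates the statistical structure the method relies on,
not arm biomechanics:

* days are 13 h at 15 Hz; each day carries 1–6 meals (Poisson, mean 3,
  clamped at 1) placed without overlap and with 3-minute clear margins;
* meal durations are log-normal with median 11 min and log-sd chosen as
  `sqrt(2·log(mean/median))` so the mean is ~14 min, truncated at 1 min —
  the right-skewed pattern (mean > median) reported for free-living meal
  logs;
* a meal is a gesture sequence: bites (3–5 s half-sine rotation bursts,
  gyro RMS well above accelerometer RMS) separated by ~16 s gaps filled
  with rest or active food-manipulation gestures (prep occupies ~18% of the
  meal, echoing reports that a sizable fraction of self-reported meals is
  spent resting or in secondary activity);
* background mixes near-still rest with cyclic 1.5–2 Hz walking, plus
  isolated bite-like confounder gestures at 2/h to exercise the detector's
  false-positive behavior;
* all randomness flows through one seeded generator per day; a master seed
  derives per-day seeds, one synthetic subject per day.

With these defaults eating occupies ~5% of the day, matching the class
imbalance the balancing step is designed for. What the generator does *not*
reproduce: real sensor units and gravity, orientation changes, secondary
activity *during* ingestion, drift, and the long tail of confusable
activities (cooking, brushing teeth, smoking). Passing the end-to-end
synthetic suite therefore demonstrates that the pipeline is implemented
coherently — that a learnable eating signature is learned, localized, and
scored correctly — not that real-world accuracy figures carry over. The
background-activity mix of real days is unpublished; our proportions are
declared assumptions and are configurable.

## Problem sizes used in the checks

The test suite validates the full pipeline at desk scale, chosen so the
whole suite runs on one CPU core in well under half an hour: 30 synthetic
days (20 train / 10 test, one subject each), a 1-minute window trained for
30 epochs, inference stride 15 (one second), detector at TS = 0.8,
TE = 0.4. On that setup the held-out balanced window accuracy exceeds 0.85,
episode TPR exceeds 0.8 with FP/TP below 1.5, and mean absolute boundary
error stays under 2 minutes; a 7.5 s window trained identically scores
visibly lower, reproducing the direction (not the magnitude) of the
window-size effect. Detector and matcher are additionally pinned to
brute-force reference implementations on 10,000 and 1,000 random cases
respectively, and label-shuffled training scores at chance on held-out
windows (the leakage canary).

## Known limitations

* Short eating episodes (snacks of a couple of minutes) are intrinsically
  hard for long windows; the default settings trade snack recall for a low
  false-positive rate. The snack-oriented operating point (shorter window,
  softer thresholds) raises recall at a steep FP/TP cost.
* The detector reports episodes only; it does not identify individual
  ingestion events inside an episode.
* Inference is whole-day batch; there is no streaming mode.
* Input is assumed to be 15 Hz; there is no resampling, unit conversion, or
  gravity separation.
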
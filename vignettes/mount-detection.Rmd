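---
title: "Detecting active mounting behavior from collar IMU signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting active mounting behavior from collar IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowmotion)
```

## The problem

Active mounting — one cow mounting another — is a key behavioral indicator
of estrus in cattle. On free-grazing farms, visual heat detection is
unreliable and labor-intensive, which motivates automatic detection from
collar-mounted inertial measurement units (IMUs). `cowmotion` implements a
complete detection pipeline for 10 Hz collar recordings: it reads a
directory-of-CSV event database, converts raw ADC counts to physical units,
rotates body-frame (BF) accelerations into the world frame (WF) using the
fused orientation quaternion, extracts a 112-dimensional feature vector per
7-second window, trains a balanced one-vs-rest linear SVM under repeated
stratified cross-validation, and statistically compares the classifier's
F1-score distribution between the two reference frames. A synthetic
five-behavior generator makes every stage testable without field data.

The scientific question behind the frame comparison: BF accelerations
depend on collar orientation, which varies across animals and across time
as the collar rotates on the neck; WF accelerations are referenced to the
ground, with gravity pinned to the z axis. If orientation variability is
nuisance rather than signal, the WF model should perform at least as well
with the same features.

## Signal model and preprocessing

Raw counts scale linearly with the configured full-scale range and ADC
resolution:

- acceleration: `a = raw * range_a / 2^bits_a * 9.807` (m/s², `range_a`
  in g),
- angular rate: `omega = raw * range_w / 2^bits_w` (°/s).

Two presets ship: BNO055 (±8 g / 14 bit accelerometer, ±2000 °/s / 16 bit
gyro) and MPU9250 (±16 g / 16 bit, ±2000 °/s / 16 bit). The scaling takes
the stated sensitivity literally as the `range` parameter. Whether a
manufacturer's "±8 g" denotes the half-span or the full span is a sensor
dialect question that cannot be settled from a datasheet quote alone, so
the presets are plain editable parameters; what the package guarantees, and
tests enforce, is consistency between encoding (`encode_raw_counts()`) and
decoding (`raw_to_accel()`, `raw_to_gyro()`): a round trip errs by at most
half an LSB.

Orientation quaternions are scalar-first `(w, x, y, z)`, right-handed,
Hamilton convention, normalized before use. `rotate_to_world()` applies the
standard quaternion rotation matrix; the rotated quantity is specific
force, i.e. gravity is retained, so a stationary collar shows ~9.807 m/s²
on WF z at any orientation. Only accelerations exist in both frames; gyro
and magnetometer channels are never rotated.

## Windowing and features

Events are segmented into fixed 7 s windows (70 samples at 10 Hz) — 7 s is
the minimum labeled event duration, so one window always captures the
event onset. By default each labeled event contributes exactly one window
(`mode = "first"`), which keeps one sample per label and matches the event
counts of the field database; `mode = "tiled"` cuts
`floor(duration/7 s)` consecutive windows for long events such as grazing.

Fourteen features are computed per channel over eight channels (the
acceleration triplet and its magnitude, the gyro triplet and its
magnitude), giving 112 features named `<channel>__<feature>` in a fixed
order so column indices are stable across runs. Conventions the package
fixes where the underlying definitions are ambiguous:

- population (divisor N) standard deviation and central moments;
  zero-variance skewness/kurtosis are defined as 0;
- the zero-crossing rate is computed on the mean-centered signal (raw
  accelerometer channels carry the gravity offset, which would otherwise
  make the feature degenerate); exact zeros count as no crossing;
- "time between maximum peaks" is the mean interval between interior
  local maxima that strictly exceed both neighboring distinct values
  (plateaus take their first index, no prominence threshold); fewer than
  two peaks yields 0;
- spectral features come from the mean-removed, untapered one-sided
  periodogram `|X_k|²/N`; the DC bin is excluded from the argmax and ties
  break toward the lower frequency. An identically-zero periodogram
  (constant signal) reports frequency 0 and density 0, which keeps the
  all-degenerate window (all features 0) self-consistent.

## Classification and evaluation

The task is one-vs-rest: active mounting (label 1) against the four other
behaviors (label 0). Because mounts are rare, the majority class is
randomly undersampled once per experiment to the mount count
(`balance_classes()`), before cross-validation — matching the narrative
order of the original analysis; leakage-averse users can balance inside
folds by calling the model functions directly.

The classifier is a linear-kernel SVM. Features are z-scored with
statistics fitted on the training portion only — a margin classifier over
mixed-unit features (m/s², °/s, Hz, dimensionless rates) needs a common
scale; this is a documented package choice and can be disabled. The cost
parameter C is grid-searched over {0.01, 0.1, 1, 10, 100} by stratified
5-fold mean F1 on a stratified 80% training split; ties go to the smallest
C (strongest regularization). Performance is then reported as the
distribution of accuracy, precision, recall and F1 over 5-fold × 20-repeat
stratified cross-validation — 100 fits — on the balanced set. Stratified
fold assignment deals each class round-robin after an independent shuffle,
so every fold's class ratio matches the global ratio within one sample.

Within one experiment the BF and WF runs consume identical events,
identical balanced row selections and identical fold assignments (all
randomness is derived from one root seed through named substreams), so the
frame comparison is paired by construction.

## Feature selection

Sequential Backward Selection starts from all 112 features and greedily
removes, at each step, the feature whose removal leaves the highest
cross-validated F1 (ties break toward the earliest column, making runs
reproducible). The evaluator is a stratified 5-fold single-repeat CV with
folds frozen per run — a full elimination path at 5×20 CV would cost ~62k
SVM fits for little ranking benefit. By default elimination runs down to a
single feature and the best subset is the global argmax along the path;
`stop_size` forces a fixed subset size instead. Permutation importance
(mean F1 drop over seeded column shuffles) is provided as a complementary,
model-agnostic relevance measure.

## Frame comparison statistics

`compare_frames()` takes the two 100-iteration F1 samples. Shapiro–Wilk
checks normality per group and the median-centered (Brown–Forsythe) Levene
test checks variance homogeneity — robust to the non-normality that F1
distributions near the ceiling typically show. If both groups pass
normality, a two-sample t-test is used (pooled if Levene passes, Welch
otherwise); otherwise the Mann–Whitney U test. The U statistic is computed
from midranks with the "U of group 1" orientation; the p-value uses exact
permutation enumeration when the smaller group has at most 8 members and
the enumeration is tractable (at most 2·10⁵ arrangements), else the normal
approximation with tie and continuity corrections. The effect size is the
rank-biserial correlation `r = 1 − 2U/(n₁n₂)`, and the difference CI is a
Hodges–Lehmann-style interval over the pairwise differences (the original
report does not state its CI method; this is the standard nonparametric
companion). Degenerate (zero-variance) groups fall through to the
nonparametric branch with a warning.

## The synthetic generator

`generate_event()` builds body-frame specific force as
`R(q)ᵀ·(0,0,9.807) + motion + noise` and world-frame channels as the exact
rotation of the body-frame channels, so frame consistency holds to machine
precision and the generator exercises the same rotation machinery the
pipeline uses in reverse. The orientation trace is a bounded random walk
(default 2 °/s wobble) around a random base orientation — an arbitrary,
drifting collar attitude. Behavior signatures are phenomenological, chosen
to match the qualitative field descriptions, with defaults fixed once:

| behavior | duration (mean ± sd, min) | body-frame motion model | gyro scale |
|---|---|---|---|
| active mounting | 9 ± 1.5 s, ≥7 | 8 m/s² peaks (~1 s) at start and end on all axes, quiet middle | 60 °/s |
| walking | 14 ± 3 s, ≥7 | 1.5 Hz sinusoid, 2 m/s² on x/y | 30 °/s |
| resting | 20 ± 4 s, ≥7 | noise only, sd 0.05 m/s² | 2 °/s |
| grazing | 71 ± 15 s, ≥10 | Poisson bursts, 1.5/s, 4 m/s² | 50 °/s |
| head nodding | 8 ± 1 s, ≥7 | 1.5 Hz sinusoid, 3 m/s² on z | 40 °/s |

Durations mirror the field database's per-class averages; amplitudes are
declared modeling assumptions, not measured values. All profiles share one
numeric field set so `interpolate_profiles()` can morph the mount
signature toward the nodding signature — the two behaviors share
short-duration vertical motion and are the natural confusion pair — which
is how the test suite demonstrates that pipeline performance degrades as
the classes converge. Magnetometer and MPU9250 channels are populated for
schema completeness only; no feature consumes them.

What the generator does *not* emulate: biomechanically realistic cattle
kinematics, real sensor noise spectra, labeling jitter, inter-animal
variability, or magnetometer miscalibration. Passing tests therefore show
that the pipeline's machinery is correct and that it separates classes
whose signatures differ the way the field descriptions say they do — they
do not certify field performance, which depends on the real labeled data.

## Numerical choices and problem sizes

- Rotation, norm-preservation and frame-consistency identities are held to
  1e-9; feature values are cross-checked against independent brute-force
  oracles at 1e-9 on 100 random windows.
- The test suite runs the full pipeline at reduced scale (14–42 events per
  class, 28–84 balanced samples) — chosen so the suite completes in well
  under a minute per experiment while keeping each class count ≥ the fold
  count; the acceptance script uses the field database's 21-mount class
  size with proportionally reduced majority classes.
- Type-I error of the two-sided Mann–Whitney test is calibrated over 2000
  null simulations at n = 25 per group (5% ± 2% band).

## Worked example

```{r example, eval = FALSE}
library(cowmotion)

recs <- generate_recordings(
  c(active_mounting = 21, walking = 40, resting = 30,
    head_nodding = 25, grazing = 20), seed = 42)
bundle <- run_experiment(run_config(seed = 42), db = recs)
cat(reproduce_report(bundle), sep = "\n")
```

The report prints the four metric means per frame, per-behavior
false-positive rates, the F1 descriptive statistics, and the
assumption-check decision path with the chosen test, p-value, rank-biserial
effect size and difference CI.

## Known limitations

- The default synthetic profiles are strongly separable; mean F1 is near 1
  on defaults, well above what noisy field data yields. Use
  `interpolate_profiles()` or edit profiles to study harder regimes.
- Balancing before (rather than inside) CV follows the original analysis
  narrative but lets the undersampling selection see all data; a per-fold
  protocol is the conservative alternative.
- The exact filename grammar and header spellings of published field
  databases vary; `parse_event_filename()` accepts a custom regex and
  `event_schema()` a header name map for this reason.
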
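# cowmotion

Detection of active mounting behavior from collar-mounted IMU signals in
free-grazing cattle.

## The problem

Active mounting — one cow mounting another — is a primary behavioral
indicator of estrus. Catching it matters: missed heats are the main cause
of failed artificial insemination, and on open pasture visual observation
is unreliable. `cowmotion` implements an end-to-end detection pipeline for
10 Hz collar IMU recordings, for researchers working on sensor-based
livestock behavior classification:

1. **Database I/O** — a directory-of-CSV event database (one folder per
   behavior class, one 26-column CSV per labeled event; behavior, cow id
   and start time encoded in the filename).
2. **Preprocessing** — linear ADC count scaling
   (`a = raw · Range_a / 2^b_a · 9.807` m/s²,
   `ω = raw · Range_ω / 2^b_ω` °/s) and rotation of body-frame (BF)
   accelerations into the world frame (WF) through the fused orientation
   quaternion: `a_WF = R(q) · a_BF`, gravity retained on WF z.
3. **Features** — 14 time/frequency statistics (mean, median, population
   std, zero-crossing rate, peak-to-peak, sum, sum of |·|, RMS, mean
   successive variation, skewness, excess kurtosis, mean time between
   local maxima, dominant periodogram frequency and density) over 8
   channels (aₓ, a_y, a_z, |a|, ωₓ, ω_y, ω_z, |ω|) per 7-s window:
   a 112-dimensional vector.
4. **Classification** — one-vs-rest linear SVM (active mount vs all other
   behaviors), majority-class undersampling, grid-searched cost C,
   metrics from the confusion matrix (accuracy, precision, recall, F1)
   over 5-fold × 20-repeat stratified cross-validation (100 fits).
5. **Feature selection** — sequential backward selection driven by
   cross-validated F1, plus permutation importance.
6. **Frame comparison** — Shapiro–Wilk and median-centered Levene
   assumption checks, then Student/Welch t or Mann–Whitney U on the
   paired BF/WF F1 distributions, with the rank-biserial effect size
   `r = 1 − 2U/(n₁n₂)`.
7. **Synthetic data** — a five-behavior signal generator (mount, walk,
   rest, graze, head-nod) with orientation random walks and raw-count
   encoding, so the full pipeline is testable without field recordings.

## Worked example

Mount and head-nodding events share short vertical motion bursts and are
the natural confusion pair. Morphing the mount profile 80% of the way
toward the nodding profile puts the synthetic task in that confusion
regime:

```r
library(cowmotion)

profiles <- default_profiles()
profiles$active_mounting <- interpolate_profiles(
  profiles$active_mounting, profiles$head_nodding, 0.8)

recs <- generate_recordings(
  c(active_mounting = 21, walking = 40, resting = 30,
    head_nodding = 25, grazing = 20), profiles = profiles, seed = 42)

bundle <- run_experiment(run_config(seed = 42), db = recs)
cat(reproduce_report(bundle), sep = "\n")
```

Output (abridged):

```
### world frame (C = 0.1)
  accuracy   89.5%
  precision  88.3%
  recall     93.9%
  f1         90.2%
  F1: mean 0.902, median 0.889, sd 0.092

  False-positive rate per non-mount behavior:
    walking          n= 40 fp=  1  2.50%
    resting          n= 30 fp=  0  0.00%
    grazing          n= 20 fp=  8  40.00%
    head_nodding     n= 25 fp=  8  32.00%

## Body vs world frame comparison
  body : mean 0.891 median 0.889 sd 0.068
  world: mean 0.902 median 0.889 sd 0.092
  shapiro body p=8.69e-08, world p=1.32e-08; levene p=0.00742 -> Mann-Whitney U
  Mann-Whitney U: statistic 4628, p = 0.346, rank-biserial 0.074
  mean diff (world - body) 0.0101, CI [0, 0.0202]
```

Reading it: each frame's section reports the mean of each metric over the
100 CV iterations and the rate at which each non-mount behavior is
misclassified as a mount — here head nodding is by far the worst offender
in the body frame (100% of its windows), exactly the confusion this regime
was built to induce, and the world-frame model is markedly more robust to
it (32%). The comparison block shows the assumption checks (both F1
distributions non-normal, so the nonparametric branch is taken) and a
frame difference that is not significant in this regime (p = 0.35,
rank-biserial 0.074).

With the default (well-separated) profiles the same pipeline reaches mean
F1 ≈ 1.0 in both frames; see the vignette
(`vignettes/mount-detection.Rmd`) for the signal models, every numerical
convention, and what the synthetic conditions do and do not demonstrate.

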
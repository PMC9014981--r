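---
title: "Methods: condition-independent rotational dynamics and submovement timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: condition-independent rotational dynamics and submovement timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cidyn)
```

## Overview

`cidyn` analyses precision center-out reaching: discrete submovements are
segmented from cursor speed, the rotational plane of condition-independent
(CI) population activity is extracted from spike trains, and the
instantaneous phase in that plane (CIφ) is evaluated as a predictor of
submovement timing against a firing-rate regression baseline. This
vignette explains the model, the tunable parameters, the numerical
choices, and what the bundled synthetic sessions can and cannot establish.

## Behavioural model and segmentation

Cursor position is sampled at 100 Hz in a 1000 × 1000 px workspace with a
central home target (radius 75 px) and 24 peripheral targets: 8 directions
at 45° crossed with three sizes (large: 250–450 px, 45° span; shallow:
325–375 px, 45°; narrow: 250–450 px, 15°).

Speed is the Euclidean norm of the derivative of the low-pass filtered
position. Parameters and rationale:

| parameter | default | units | role |
|---|---|---|---|
| `cutoff_hz` | 10 | Hz | first-order Butterworth, run forward and backward for zero phase lag |
| `peak_threshold` | 250 | px/s | minimum speed peak height |
| `prom_frac` | 0.5 | – | prominence must reach this fraction of peak height |
| `initial_dist_px` | 150 | px | minimum movement-end distance from center for the initial submovement |

Prominence is the height of a peak above the larger of its two adjacent
troughs, a trough being the minimum before the nearest strictly larger
sample on that side. Ties across plateaus break toward the earlier sample.
Numerical choices where the procedure is underdetermined: the filter uses
reflect-padding at the trial edges (the `signal` package's `filtfilt`
zero-pads, which distorts trials not starting at rest); half-maximum
onset/offset times are linearly interpolated between samples to avoid
10-ms quantisation; "movement end" for the 150-px rule is the cursor
position at the half-max offset. All statistics are computed from the
filtered speed; the raw speed is exposed only for display.

## The CI plane and CIφ

Spike trains are binned at 10 ms, converted to rates, smoothed with a
Gaussian kernel (σ = 30 ms, truncated at ±4σ and renormalised so edge
bins conserve mass), and square-root transformed to equalise variance
across high- and low-rate units. Smoothing is applied to counts before the
square root; the raw smoothed rates are kept alongside because the plane
alignment and the regression baseline are defined on raw rates.

The CI trajectory is the per-unit average across *all* movements
regardless of direction or target size, aligned on speed peaks
(window −500…+300 ms). Averaging over balanced conditions cancels cosine
direction tuning, leaving the timing-carrying CI component. After
centering and projection onto the top 6 principal components, the
dynamics matrix is fit by least squares under a skew-symmetry constraint:
minimising ‖Ẋ − MX‖ over skew M solves the Lyapunov-type equation
`S M + M S = Ẋ Xᵀ − X Ẋᵀ` with `S = X Xᵀ`, solved exactly in the
eigenbasis of S. Derivatives are central differences (wrap-around when the
trajectory is a closed phase cycle). Eigenvalues of M are purely
imaginary; each conjugate pair spans a candidate rotation plane.

**Plane selection.** Candidate planes are ranked by *rotational activity*
— the variance the plane captures times its angular velocity |Im λ| — and
the top plane is taken. Ranking by |Im λ| alone is unstable on
phase-averaged trajectories: a near-degenerate low-variance pair driven by
bin noise can wobble faster than the population cycle that carries
essentially all the variance, and the literal rule then selects noise.
The variance-weighted score reduces to the same choice whenever a single
strong rotation dominates (all planted-rotation tests), and keeps the
iteration below convergent.

**Axis conventions.** Within the plane, the rotation sign is set so the
average phase velocity is positive (counter-clockwise; CIy lags CIx by
π/2), then +CIx is rotated onto the direction of maximal population
firing rate. The rate-vs-angle profile is estimated in 36 bins of 10°
(the generic "100 angle intervals" reading; bin count only sets alignment
granularity and is configurable), empty bins interpolated circularly.
Because the phase that downstream analysis consumes is the *Hilbert*
phase, not the geometric angle — and the two differ measurably for
non-sinusoidal cycles — alignment finishes with two refinement rotations
that bin the population rate by CIφ itself and rotate the plane so the
maximum-rate phase is zero. The preferred phase is estimated from the
profile's first circular harmonic (rate-weighted resultant), the standard
preferred-phase estimator, rather than the argmax bin: on a broad noisy
profile the argmax jumps by whole bins (±10° ≈ ±15 ms at a 570-ms cycle)
while the first harmonic is stable.

CIφ itself is the circular mean of φx and φy + π/2, where φx, φy are the
analytic-signal angles of the per-segment mean-subtracted CIx and CIy.
The Hilbert transform is applied per contiguous recording segment (per
trial in practice); segments shorter than 10 samples get missing phase.

**Iteration.** Event-aligned averaging presumes the events are the right
anchor; to relax this, the plane is refit on rates re-averaged within 36
CIφ bins (occupancy-weighted means, empty bins interpolated circularly,
the binned trajectory treated as one closed cycle), for 3 fits total.
The principal angle between successive planes is logged; an increase
triggers a warning and returns the last iterate. On recording-scale
synthetic sessions (100 units) the angle drops to a few degrees by the third fit;
at 30 units convergence is noisier, which is visible in the iteration log.

**Cross-validation.** Trials are partitioned into k = 5 seeded folds; the
plane is fit on 4/5 of trials and held-out trials are projected into it.
All reported timing results use held-out phase.

## Timing models and evaluation

The CIφ model predicts each submovement at the upward zero crossing of
CIφ (wrap-aware, linearly interpolated) within −300…+100 ms of the speed
peak; with several crossings, the latest one before the peak wins, else
the earliest after. The comparator regresses peak speed on per-unit rates
averaged over the same window (ordinary least squares, no per-unit lags)
and predicts via local maxima of the weighted instantaneous rate signal
under the mirrored multiple-candidate rule. Submovements with no
candidate in the window are *unaligned*. Models are compared on the
identical submovement set by the SD of aligned offsets with a two-sided
variance-ratio F test (normality is an assumption; n ≥ 3 per group
enforced) and by unaligned fractions. The regression is fit in-sample per
session; a cross-validated mode exists for symmetry but is not the
default, since the comparison of record is between timing SDs.

Circular statistics are self-contained: circular mean/SD via the first
trigonometric moment (SD = √(−2 ln R)), the Rayleigh test with the
standard analytic p approximation (verified against a Monte-Carlo oracle
in the test suite), and the circular–linear correlation
r = √((r²cs + r²ss − 2 rcs rss rcc)/(1 − r²cc)) with the χ²(2)
approximation for significance.

## The synthetic-session generator

No public recording accompanies this analysis, so the generator *is* the
study condition. It emulates: bell-shaped (Gaussian) speed profiles;
corrective peak speeds averaging one-third of initial (lognormal jitter,
SD 0.12); 8 × 3 balanced target conditions presented in a fixed cycle;
inter-peak intervals from a 300-ms-shifted gamma (shape 3, scale 90;
mean 570 ms); per-unit baselines 5–20 spikes/s; rate bumps leading each
speed peak by unit-specific lags (uniform, default −200…0 ms) with
amplitude proportional to peak speed (gain 0.008–0.03 (sp/s)/(px/s)) and
cosine direction tuning (depth 0–0.5); inhomogeneous Poisson spiking at
1-ms resolution by rate rectification. A single master seed fans out to
per-trial and per-unit substreams, so adding trials never perturbs
earlier ones and sessions are bit-reproducible.

A Gaussian speed bump ties displacement, peak speed and duration together
(d = v·σ·√2π), so the three cannot all be configured independently. The
generator draws peak speeds from the configured distribution (making the
⅓ corrective ratio hold by construction), takes displacements from the
target geometry — corrective trials undershoot so the corrective's
acceleration phase starts outside the target, guaranteeing
classifiability — and derives each bump's FWHM. Realised medians land
near the nominal 230 ms (initial) and 200 ms (corrective), inside the
100–350 ms range typical of such movements. Trial-to-trial gain noise is
available (`gain_noise_sd`) but off by default, as no variability model
is dictated by the data the generator emulates.

What the generator does *not* emulate: non-Poisson spiking statistics,
correlated noise across units, non-cosine tuning, reaction-time
variability structure, measurement noise on the cursor (available but
default 0), EMG/biomechanics, or electrode artifacts. Passing tests on
synthetic sessions therefore demonstrate parameter recovery and internal
consistency of the algorithms — not that real M1 data behave this way.

## Known limitations and observed behaviour

- With desk-scale populations (30 units) the sampled gain-weighted mean
  unit lag has SD ≈ 12 ms around the configured mean, and per-session
  lead-time estimates inherit that spread; recovery tests therefore use
  100-unit sessions (the scale of a real recording session), where the
  cross-validated mean CIφ = 0 crossing lands within a few ms of the
  planted lead.
- Corrective cycles are smaller and faster than initial ones, and their
  phase zero sits ~10–15 ms earlier relative to their rate crest — a
  class-dependent phase-slope difference analogous to what is seen in
  recorded data. Both classes stay within ±20 ms of the planted lead.
- A small fraction (≲1%) of submovements has no upward CIφ = 0 crossing
  in the evaluation window (the phase hovers above zero after a shallow
  reversal); the rate baseline, whose candidates are any local maxima of
  a smoothed noisy signal, essentially never lacks one in a 400-ms
  window. The unaligned-fraction comparison between the models is
  therefore uninformative under this generator, while the SD comparison
  robustly favours the phase model.
- Mean offsets over the bounded −300…+100 ms window are reported as plain
  means; for the concentrated distributions produced here they coincide
  with circular means on the window mapped to a cycle.

## Problem sizes

Default analyses in the examples, tests and the acceptance script use
sessions of 100–200 trials with 30–100 units, 10-ms bins and 5-fold
cross-validation; these sizes were chosen as the smallest at which the
sampling noise of the generated condition no longer dominates the
quantities under test.
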
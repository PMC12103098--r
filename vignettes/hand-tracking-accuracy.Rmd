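---
title: "Comparing hand-tracking systems: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing hand-tracking systems: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handtrackr)
```

## The problem

Markerless hand-tracking cameras are attractive for rehabilitation because
they are cheap and contactless, but before they can replace marker-based
motion capture in assessment, their per-landmark accuracy during clinically
meaningful tasks has to be quantified. `handtrackr` implements a comparison
pipeline for paired recordings of the same trial by two systems: a
"reference" (uniformly sampled, motion-capture-grade) and a "camera"
(nonuniformly sampled, noisier) stream of 20 hand landmarks, 60 position
signals in millimetres.

Two tasks are covered: a Kapandji variant (thumb opposition — the thumb tip
touches the index, middle, ring and pinky fingertips once each, in order)
and finger abduction/adduction (periodic splay of the extended fingers).
Both exercise the full range of finger/thumb flexion-extension and
abduction-adduction that everyday device interactions are built from.

## Comparison measures

Conventional measures operate per signal over the matched samples:
Pearson correlation `corr_i` (averaged into `corr_signal`) and mean absolute
error `MAE_i` (averaged into `MAE_avg`, mm). They are complementary and
individually incomplete: an amplitude offset preserves correlation but
inflates MAE; a temporal lag degrades correlation while MAE may stay low.
Three further views probe specific failure modes:

* `corr_fingertip` — correlations of four task-specific inter-fingertip
  Euclidean distances (thumb-to-each-tip for Kapandji, neighbouring tips for
  abduction/adduction). Distances are invariant to rigid translation of
  either system, so this isolates hand-shape tracking from frame
  calibration.
* Segment-length errors — proximal/middle/distal phalanx lengths of the
  four fingers, measured at the mid-trial frame and differenced between
  systems. This evaluates the tracker's internal hand model; the signed
  error distinguishes systematic underestimation. The thumb is excluded
  because its MCP landmark is not tracked.
* Static/dynamic parameters — hand size (wrist to middle MCP in the flat
  pose), mean wrist height above the table, and task speed (mean
  finite-difference speed of the thumb tip for Kapandji, index tip for
  abduction/adduction), available as covariates for downstream group
  analyses.

### Latent-space comparison

The high-dimensional alternative to signal-by-signal comparison: the two
m×n matrices are row-stacked (reference first) and each signal is min-max
normalized over the combined 2m rows, so both systems share one scale per
signal and every signal contributes equally regardless of amplitude. One PCA
is fitted to the stacked, mean-centered matrix; both halves are projected
with the *same* loadings onto the two leading components. The camera
projection is then translated so its latent means match the reference's
(the recorded offsets expose constant latent displacement), and `corr2d`
scores the similarity of the encodings.

Operational choices the underlying idea leaves open, fixed here:

* `corr2d` is the unweighted mean of the per-dimension Pearson correlations
  over matched samples. Correlating dimensions separately keeps the measure
  translation-invariant per dimension and symmetric in the two components; a
  VAF-weighted variant is available (`corr2d(lc, vaf_weighted = TRUE)`) for
  when the second component is marginal.
* Columns are mean-centered *after* min-max normalization — normalization
  alone does not center, and uncentered PCA would devote the first component
  to the column means.
* VAF is computed for the combined fit (both systems together), matching how
  the projection is produced; k = 2 components are retained and the
  cumulative VAF(2) gates trial quality (batch fits discard trials below
  90% by default).
* Component signs follow a fixed convention — the largest-magnitude loading
  of each component is positive — so projections are reproducible across
  runs and linear-algebra backends. `corr2d` is invariant to a simultaneous
  sign flip anyway, since both systems share loadings.
* PCA treats samples as exchangeable points: the temporal order never enters
  the fit, so a temporal lag appears as shape distortion of the trajectory
  in latent space, not as a shift.

Across a batch of trials, `batch_relationship()` regresses `corr2d` on
`corr_signal` (OLS) with and without the VAF filter; the slope's sign and
the filter's effect on R² are the qualitative fingerprints to check against
real cohorts.

## Preprocessing

Clipping to the co-tracked span happens first, then the camera stream is
resampled onto the reference's (already clipped) timestamps; clipping first
avoids interpolating through untracked stretches. Interpolation is linear:
it assumes nothing about the signal family, is exact for signals affine in
time, and its error is bounded by `max|f''|·h²/8` on smooth signals at
sampling step h — at 50 Hz and hand-movement frequencies this is far below
tracker noise. No extrapolation is ever performed; reference timestamps
outside the camera's retained span are dropped.

Coordinate alignment is translation-only: one constant (x, y, z) vector
makes the camera's index-MCP equal the reference's at the first common
sample. Relative orientation is assumed to have been aligned at device
calibration, so no rotational (Procrustes) registration is applied —
deliberately, since a rotation estimated per trial would absorb genuine
tracking error. "First analysis instance" is interpreted as the first common
timestamp after clipping. Trials with an unusable thumb-CMC marker are
handled by dropping the three CMC columns from both systems (n = 57).

Degenerate signals: a constant signal has no defined correlation — it is
excluded from `corr_signal` and counted (`n_undefined`) rather than scored
as 0, which would bias the average downward; min-max normalization instead
*errors* on a constant column, since the latent method cannot represent it.

## The synthetic generator

The generator exists so every stage of the pipeline can be exercised and
tested without participant recordings. It is a parametric forward-kinematic
model, not a biomechanical simulation.

**Geometry** (`hand_spec()`, defaults in mm, an average adult hand): hand
size 95 (wrist to middle MCP), palm width 80; per-finger
proximal/middle/distal phalanges 40/25/22 (index), 45/28/24 (middle),
42/27/24 (ring), 33/20/20 (pinky); thumb metacarpal 45, proximal 35, distal
30. The thumb is a two-link chain (CMC→IP = metacarpal + proximal, IP→tip =
distal) because the thumb MCP is not among the tracked landmarks.

**Kinematics.** Fingers flex in planar chains with fixed 1 : 0.8 : 0.5
MCP/PIP/DIP angle coupling plus one abduction angle per finger; the palm
stays parallel to the table (per task instructions) 150 mm above the device.
The thumb is driven by closed-form two-link inverse kinematics toward a
scripted tip target, which makes the Kapandji touches *exact*: each touch
target is the actual fingertip position at the touch frame, solved once per
finger so the contact happens at a comfortable thumb reach (82% of full
thumb length). Segment lengths are conserved to numerical precision in
every frame by construction — the property the segment-length metrics rely
on.

**Tasks** (`task_script()`): 10 s at 50 Hz by default (self-paced tasks of
this kind run on the order of ten seconds; the rate matches common
motion-capture exports). Kapandji touch times sit at 18/38/58/78% of the
trial with cosine-squared flexion bumps of ±12% width; all fingers
additionally share a low common flexion envelope (amplitude 0.6 of each
finger's touch angle), reflecting the strong inter-finger coupling — the
movement synergies — of real hand motion. Abduction/adduction oscillates the
finger splay (±0.18 rad, 3 cycles) with gains graded across fingers and an
opposing thumb swing. Angle ranges outside anatomical caps (flexion
1.9 rad, abduction 0.45 rad) are rejected at script construction. A small
postural sway (default 2 mm, sub-Hz, one shared oscillation translating the
whole hand rigidly) emulates the ever-present drift of a real limb; it is
rank-one by design — postural drift moves the arm as a unit — and it
guarantees no signal is exactly constant, as in real recordings.
`amplitude_scale = 0` switches everything off and yields the exactly static
flat pose used to measure hand size.

**Degradation** (`degradation_spec()`) applies, in a fixed order: proximal
phalanx shortening (PIP pulled toward MCP, distal landmarks riding along —
only the proximal segment shortens), temporal lag on the timestamps,
i.i.d. Gaussian noise per sample and signal with variance set from the
requested SNR (`10·log10(var(signal)/var(noise))`, signal power about the
per-signal mean — the convention matching variance-based SNR estimation on
detrended signals), amplitude offset (scalar or per-axis), and uniform
timestamp jitter of interior samples (< half the sampling interval, so
timestamps stay strictly increasing). The order is fixed and documented
rather than configurable; the perturbation experiments apply one stage at a
time anyway. All draws are governed by the spec's seed and leave the
caller's RNG untouched.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: occlusion and marker dropout, soft-tissue and
skin-motion artifact, the stereo-IR image pipeline and its hand-model
fitting biases (beyond the single proximal-length bias), interaction of
tracking quality with skin tone or lighting, tremor and pathological
movement patterns, and non-rigid palm deformation. Results on synthetic
cohorts validate the *pipeline's* correctness and the qualitative behaviour
of its measures under controlled degradations; they are not evidence about
any particular device's accuracy.

## Numerical and degenerate-input choices

* Pearson is used wherever "correlation" is unqualified — standard for
  signal agreement and consistent with the translation-invariance arguments
  above.
* Speed uses first-order finite differences on the common time base.
* The mid-trial frame for segment lengths is `floor(m/2)`.
* The Kapandji contact tolerance is 5 mm — needed to make "touch" testable;
  the IK construction beats it by many orders of magnitude.
* `batch_relationship()` refuses batches where `corr_signal` has zero
  variance (e.g. all-identity manifests): the fit would be meaningless.
* Per-axis MAE (60 signals) is the primary error measure; a per-landmark 3D
  Euclidean error (`landmark_mae_3d()`) is provided as a clearly separate
  extra, since the two summaries differ (an axis-aligned offset of 3 mm
  gives per-axis MAE 1 mm but 3D error 3 mm).

## Study conditions used in the shipped analyses

The numbered drivers under `analysis/` and the acceptance script use: 10 s
trials at 50 Hz; a degradation grid of SNR {50, 40, 30} dB crossed with lags
{0, 0.15, 0.3, 0.5} s and 20% timestamp jitter, three replicates per cell
and task (72 trials) — lags in this range produce the broad spread of
per-trial agreement (roughly 0.7–1.0 in `corr_signal`) that makes the
corr2d-vs-corr_signal regression informative, while SNR alone moves
correlations only in the third decimal; 100-seed replications for the
noise-ordering experiment; and a 101 s trial (> 5000 samples) for SNR
calibration, where the realized-SNR estimator's sampling error is well
below the ±1 dB check band. Monte-Carlo property tests in the suite use 20
replicates.

## Known limitations

The kinematic model is planar per finger and rigid at the palm; it cannot
represent opposition roll of the thumb pad, palm arching, or out-of-plane
finger deviation. The latent comparison inherits PCA's linearity and
orthogonality constraints — hand tasks have correlated, non-orthogonal
components, and two components capture only part of the variance for the
sequential Kapandji task; nonlinear or temporal dimensionality reduction is
out of scope here. The `corr2d` definition compares dimensions separately
and does not capture rotations of one encoding relative to the other beyond
penalizing them; that is intentional (shared loadings make rotation a real
discrepancy), but worth remembering when interpreting values near zero.
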
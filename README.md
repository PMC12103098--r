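# handtrackr

Accuracy assessment of markerless hand tracking against marker-based motion
capture, for researchers and clinicians validating low-cost hand-tracking
cameras (Leap-style stereo-IR devices) as rehabilitation and assessment
tools.

Two tracking systems record the same trial — timestamped 3D positions (mm)
of 20 hand landmarks (wrist; thumb CMC/IP/tip; MCP/PIP/DIP/tip of the four
fingers), i.e. 60 scalar signals — during two range-of-motion tasks: a
Kapandji variant (thumb tip touches each fingertip once, index → pinky) and
finger abduction/adduction (periodic splay of the extended fingers).
`handtrackr` quantifies how well the camera system reproduces the reference
recording, with conventional per-signal statistics and with a joint-PCA
latent-space comparison. Because such paired recordings are rarely
shareable, the package includes a forward-kinematic synthetic generator and
a parametric degradation model, so the whole pipeline runs, and is tested,
without any participant data.

## Methods at a glance

**Preprocessing.** Trials are clipped to the co-tracked span, the camera's
nonuniformly sampled stream is linearly resampled onto the reference's
uniform time base, and the camera frame is translated so both systems'
index-MCP positions coincide at the first common sample.

**Conventional metrics.** With `n` matched signals (60, or 57 when the thumb
CMC marker is unusable):

- per-signal Pearson correlation `corr_i`, summarized as
  `corr_signal = (1/n) Σ corr_i`;
- per-signal mean absolute error
  `MAE_i = (1/t_last) Σ_t |cam_i(t) − ref_i(t)|` (mm), summarized as
  `MAE_avg = (1/n) Σ MAE_i`;
- `corr_fingertip`: correlations of the four task-specific inter-fingertip
  Euclidean distances (thumb→each fingertip for Kapandji, neighbouring tips
  for abduction/adduction), a 60D → 4D functional reduction;
- phalanx-length errors: proximal/middle/distal segment lengths of the four
  fingers (12 values) compared between systems at a mid-trial frame;
- static and dynamic trial parameters: hand size (wrist to middle MCP in the
  flat pose), mean wrist height, and task speed (thumb-tip or index-tip).

**Latent comparison.** The two m×n trial matrices are row-stacked and each
signal min-max normalized over the combined 2m rows,
`x_norm,i = (x_i − min x_i) / (max x_i − min x_i)`. A single PCA is fitted to
the stacked matrix so both systems share loadings; both halves are projected
onto the two leading components, the camera projection is shifted so its
per-dimension latent means match the reference's, and `corr2d` — the mean of
the per-dimension Pearson correlations between the projections — scores the
similarity of the two encodings. The two-component variance accounted for
(VAF) measures how faithfully 2D summarizes the trial; batch analyses relate
`corr2d` to `corr_signal` by OLS, optionally discarding trials with
VAF < 90%.

**Synthetic data.** A parametric hand (segment lengths, palm width, hand
size) moves through scripted tasks via planar finger flexion chains
(1 : 0.8 : 0.5 MCP/PIP/DIP coupling), per-finger abduction, and a two-link
thumb driven by closed-form inverse kinematics — Kapandji touches are exact
by construction. The degradation model applies, in order: proximal phalanx
shortening, temporal lag, Gaussian noise at a target SNR
(`10·log10(signal var / noise var)` dB), amplitude offsets, and timestamp
jitter. Everything is deterministic under a seed.

## Worked example

```r
library(handtrackr)
spec <- hand_spec()                                   # 95 mm hand, right
ref  <- generate_trajectory(spec, task_script("kapandji", duration = 10))
cam  <- degrade(ref, degradation_spec(snr_db = 40, lag_s = 0.2,
                                      proximal_bias_mm = 15, seed = 7))
pair <- preprocess_pair(ref, cam)
accuracy_report(pair)
latent_compare(pair)
```

```
<accuracy_report> task=kapandji hand=right participant=synthetic (60 signals)
  corr_signal = 0.9569 (0 undefined), mae_avg = 4.955 mm
  corr_fingertip: TI=0.948 TM=0.944 TR=0.958 TP=0.960
  mean |segment error| = 5.128 mm; wrist height 150.0 mm; speed 28.6 mm/s
<latent_comparison> 491 samples/system, k = 2
  VAF: 0.517 + 0.280 (cumulative 0.797)
  latent offsets: -0.2502, 0.4574; corr2d = 0.9742
```

Reading this: a 200 ms tracking lag plus 40 dB noise pulls the mean signal
correlation down to 0.957 and costs ~5 mm of MAE; the injected 15 mm
proximal-phalanx bias dominates the mean segment error (the proximal rows of
`$segment_errors` sit at 15 mm, middle/distal near 0); and the 2D encodings
remain highly correlated (`corr2d` = 0.974) with 80% of the combined
variance captured by two components.

The `analysis/` directory holds the numbered drivers that walk the full
study — `01_simulate.R` (synthetic cohort), `02_conventional_metrics.R`,
`03_latent_comparison.R` (including the noise/offset/novel-task perturbation
experiments), `04_cohort_relationship.R` (the corr2d-vs-corr_signal
regression with and without the VAF ≥ 90% filter) — writing their tables
under `results/`. The methods vignette
(`vignettes/hand-tracking-accuracy.Rmd`) documents the model, parameter
defaults, and design choices.

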
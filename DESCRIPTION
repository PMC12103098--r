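Package: handtrackr
Title: Accuracy Assessment of Markerless Hand Tracking Against Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying the agreement between two hand-tracking
    systems that stream timestamped 3D positions of 20 hand landmarks (60
    signals per trial). Provides a parametric forward-kinematic hand model and
    task generator (Kapandji thumb opposition, finger abduction/adduction) with
    a configurable degradation model (additive Gaussian noise at a target SNR,
    amplitude offsets, temporal lag, sampling jitter, proximal phalanx length
    bias); preprocessing (overlap clipping, resampling of nonuniform streams,
    translational coordinate alignment); conventional accuracy metrics
    (per-signal Pearson correlations, mean absolute errors, inter-fingertip
    distance correlations, finger segment-length errors, static and dynamic
    trial parameters); and a joint principal-component latent-space comparison
    (min-max normalization of the stacked two-system matrix, shared loadings,
    variance accounted for, latent mean alignment, 2D projection correlation)
    together with batch study orchestration and aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
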
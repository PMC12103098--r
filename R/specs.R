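#' Parametric hand geometry
#'
#' Segment lengths of an adult hand used by the forward-kinematic generator.
#' Fingers (index, middle, ring, pinky) carry proximal (MCP–PIP), middle
#' (PIP–DIP) and distal (DIP–tip) phalanx lengths. The thumb is modelled as a
#' two-link chain: CMC to IP (metacarpal + proximal phalanx combined, since the
#' thumb MCP landmark is not tracked) and IP to tip (distal phalanx).
#'
#' @param hand_size Wrist to middle-MCP distance (mm); the study's static hand
#'   size parameter.
#' @param palm_width Breadth across the four finger MCPs (mm).
#' @param proximal,middle,distal Named numeric vectors of phalanx lengths (mm)
#'   for `index`, `middle`, `ring`, `pinky`.
#' @param thumb Numeric vector with elements `metacarpal`, `proximal`,
#'   `distal` (mm).
#' @param hand `"right"` or `"left"`.
#' @return Object of class `hand_spec`.
#' @export
#' @examples
#' spec <- hand_spec()
#' spec$hand_size
hand_spec <- function(hand_size = 95,
                      palm_width = 80,
                      proximal = c(index = 40, middle = 45, ring = 42, pinky = 33),
                      middle   = c(index = 25, middle = 28, ring = 27, pinky = 20),
                      distal   = c(index = 22, middle = 24, ring = 24, pinky = 20),
                      thumb    = c(metacarpal = 45, proximal = 35, distal = 30),
                      hand = c("right", "left")) {
  hand <- match.arg(hand)
  fing <- finger_names()
  for (v in list(proximal, middle, distal)) {
    if (!all(fing %in% names(v)))
      stop("phalanx length vectors must be named index/middle/ring/pinky",
           call. = FALSE)
  }
  if (!all(c("metacarpal", "proximal", "distal") %in% names(thumb)))
    stop("thumb lengths must be named metacarpal/proximal/distal", call. = FALSE)
  lens <- c(hand_size, palm_width, proximal[fing], middle[fing], distal[fing], thumb)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all hand dimensions must be strictly positive and finite", call. = FALSE)
  if (hand_size <= max(proximal[fing], middle[fing], distal[fing]))
    stop("hand_size must exceed the longest phalanx", call. = FALSE)
  structure(
    list(hand_size = unname(hand_size), palm_width = unname(palm_width),
         proximal = proximal[fing], middle = middle[fing], distal = distal[fing],
         thumb = thumb[c("metacarpal", "proximal", "distal")], hand = hand),
    class = "hand_spec")
}

#' Task script for the synthetic generator
#'
#' Describes one trial of either task: `"kapandji"` (the thumb tip touches the
#' index, middle, ring and pinky fingertips once each, in that order) or
#' `"abd_add"` (the extended fingers splay apart and together periodically).
#' `amplitude_scale = 0` yields a perfectly static flat pose (used for
#' hand-size measurement and as a degenerate fixture).
#'
#' @param task `"kapandji"` or `"abd_add"`.
#' @param duration Trial length (s).
#' @param rate Sampling rate (Hz); the generator samples uniformly.
#' @param amplitude_scale Multiplier in `[0, 1]` on all task angle excursions.
#' @param flexion_max Upper bound on the MCP flexion angle (rad) the script is
#'   allowed to command; anatomical cap 1.9 rad.
#' @param abduction_amp Half-range of per-finger MCP abduction oscillation
#'   (rad) for the abduction/adduction task; anatomical cap 0.45 rad.
#' @param cycles Number of splay cycles per trial (abduction/adduction).
#' @param sway_mm Amplitude of the slow postural sway of the whole hand (mm);
#'   deterministic, scaled by `amplitude_scale`.
#' @return Object of class `task_script`.
#' @export
task_script <- function(task = c("kapandji", "abd_add"),
                        duration = 10, rate = 50,
                        amplitude_scale = 1,
                        flexion_max = 1.6,
                        abduction_amp = 0.18,
                        cycles = 3,
                        sway_mm = 2) {
  task <- match.arg(task)
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (amplitude_scale < 0 || amplitude_scale > 1)
    stop("amplitude_scale must lie in [0, 1]", call. = FALSE)
  if (flexion_max <= 0 || flexion_max > 1.9)
    stop("anatomically impossible flexion range: flexion_max must lie in (0, 1.9] rad",
         call. = FALSE)
  if (abduction_amp < 0 || abduction_amp > 0.45)
    stop("anatomically impossible abduction range: abduction_amp must lie in [0, 0.45] rad",
         call. = FALSE)
  if (sway_mm < 0) stop("sway_mm must be >= 0", call. = FALSE)
  structure(
    list(task = task, duration = duration, rate = rate,
         amplitude_scale = amplitude_scale, flexion_max = flexion_max,
         abduction_amp = abduction_amp, cycles = cycles, sway_mm = sway_mm,
         touch_order = finger_names()),
    class = "task_script")
}

#' Degradation model for the synthetic camera system
#'
#' Error process applied to a clean reference trajectory to emulate a
#' camera-based tracker. Stages are applied in a fixed order: proximal phalanx
#' length bias (in the kinematic chain), temporal lag (timestamps), additive
#' Gaussian noise at a target SNR, amplitude offset, then timestamp jitter
#' (nonuniform sampling). All stochastic draws are fixed by `seed`.
#'
#' @param snr_db Target signal-to-noise ratio in dB
#'   (`10*log10(signal power / noise variance)`, signal power taken as the
#'   per-signal variance about its mean), or `NULL` for no noise.
#' @param offset_mm Amplitude offset: a scalar added to all 60 signals, or a
#'   length-3 `(x, y, z)` vector added per axis, or `NULL`.
#' @param lag_s Temporal lag (s) added to the camera timestamps; must be >= 0.
#' @param jitter_frac Uniform timestamp jitter as a fraction of the sampling
#'   interval, in `[0, 0.5)`; interior timestamps are perturbed.
#' @param proximal_bias_mm Shortening of each finger's proximal phalanx (mm)
#'   propagated down the kinematic chain, emulating a biased hand model.
#' @param seed Integer seed fixing the noise and jitter draws.
#' @return Object of class `degradation_spec`.
#' @export
degradation_spec <- function(snr_db = NULL, offset_mm = NULL, lag_s = 0,
                             jitter_frac = 0, proximal_bias_mm = 0, seed = 1L) {
  if (!is.null(snr_db) && !is.finite(snr_db))
    stop("snr_db must be finite (or NULL for no noise)", call. = FALSE)
  if (!is.null(offset_mm)) {
    if (!length(offset_mm) %in% c(1L, 3L) || any(!is.finite(offset_mm)))
      stop("offset_mm must be a finite scalar or length-3 (x, y, z) vector",
           call. = FALSE)
  }
  if (!is.finite(lag_s) || lag_s < 0) stop("lag_s must be >= 0", call. = FALSE)
  if (!is.finite(jitter_frac) || jitter_frac < 0 || jitter_frac >= 0.5)
    stop("jitter_frac must lie in [0, 0.5)", call. = FALSE)
  if (!is.finite(proximal_bias_mm) || proximal_bias_mm < 0)
    stop("proximal_bias_mm must be >= 0", call. = FALSE)
  structure(
    list(snr_db = snr_db, offset_mm = offset_mm, lag_s = lag_s,
         jitter_frac = jitter_frac, proximal_bias_mm = proximal_bias_mm,
         seed = as.integer(seed)),
    class = "degradation_spec")
}
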
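#' Degrade a trajectory into a synthetic camera-system recording
#'
#' Applies the degradation model to a clean, uniformly sampled trajectory, in
#' this fixed order:
#' 1. proximal phalanx bias — each finger's PIP is pulled toward its MCP by
#'    `proximal_bias_mm`, and the DIP and tip ride along, so only the proximal
#'    segment shortens (emulating a tracker whose hand model underestimates
#'    proximal phalanges);
#' 2. temporal lag — `lag_s` is added to the timestamps;
#' 3. additive Gaussian noise — per-signal variance chosen so that
#'    `10*log10(var(signal) / var(noise)) = snr_db`, with the signal power
#'    taken about the per-signal mean;
#' 4. amplitude offset — a scalar added to all signals, or a per-axis
#'    `(x, y, z)` vector;
#' 5. timestamp jitter — interior timestamps perturbed uniformly by up to
#'    `jitter_frac` of the sampling interval (nonuniform sampling).
#'
#' All randomness is fixed by the spec's seed; the caller's RNG state is left
#' untouched.
#'
#' @param traj A uniformly sampled [trajectory()].
#' @param d A [degradation_spec()].
#' @return A degraded [trajectory()] tagged `system = "camera"`.
#' @export
degrade <- function(traj, d) {
  stopifnot(inherits(traj, "hand_trajectory"), inherits(d, "degradation_spec"))
  pos <- traj$positions
  time <- traj$time

  if (d$proximal_bias_mm > 0)
    pos <- apply_proximal_bias(pos, d$proximal_bias_mm)

  if (d$lag_s > 0) time <- time + d$lag_s

  with_seed(d$seed, {
    if (!is.null(d$snr_db)) {
      sig_var <- apply(pos, 2, stats::var)
      flat <- sig_var <= 0
      if (any(flat))
        stop("cannot set an SNR on constant (zero-power) signal(s): ",
             paste(colnames(pos)[flat], collapse = ", "), call. = FALSE)
      noise_sd <- sqrt(sig_var / 10^(d$snr_db / 10))
      noise <- matrix(stats::rnorm(length(pos)), nrow(pos), ncol(pos))
      pos <- pos + sweep(noise, 2, noise_sd, "*")
    }
    if (!is.null(d$offset_mm)) {
      off <- if (length(d$offset_mm) == 1L) rep(d$offset_mm, ncol(pos))
             else rep_len(d$offset_mm, ncol(pos))  # x,y,z cycle matches column order
      pos <- sweep(pos, 2, off, "+")
    }
    if (d$jitter_frac > 0 && length(time) > 2) {
      dt <- mean(diff(time))
      n_in <- length(time) - 2L
      time[2:(length(time) - 1L)] <- time[2:(length(time) - 1L)] +
        stats::runif(n_in, -1, 1) * d$jitter_frac * dt
    }
  })

  trajectory(time, pos, system = "camera", task = traj$task,
             hand = traj$hand, participant = traj$participant)
}

# shorten each finger's proximal phalanx by `bias` mm, translating the distal
# landmarks with the PIP so middle and distal segment lengths are untouched
apply_proximal_bias <- function(pos, bias) {
  nm <- colnames(pos)
  for (f in finger_names()) {
    mcp <- pos[, landmark_cols(paste0(f, "_mcp"), nm), drop = FALSE]
    ci_pip <- landmark_cols(paste0(f, "_pip"), nm)
    pip <- pos[, ci_pip, drop = FALSE]
    seg <- pip - mcp
    len <- row_norms(seg)
    if (any(len <= bias))
      stop("proximal bias of ", bias, " mm exceeds the ", f,
           " proximal segment length", call. = FALSE)
    shift <- -bias * seg / len
    for (j in c("pip", "dip", "tip")) {
      ci <- landmark_cols(paste0(f, "_", j), nm)
      pos[, ci] <- pos[, ci] + shift
    }
  }
  pos
}

#' Generate a matched (reference, camera) trial pair
#'
#' Convenience fixture builder: generates a clean reference trajectory and a
#' degraded camera copy of the same trial, optionally writing both to
#' trajectory files.
#'
#' @inheritParams generate_trajectory
#' @param d A [degradation_spec()]; its `seed` field is overridden by `seed`.
#' @param seed Integer seed for the degradation draws.
#' @param dir Optional directory; when given, `ref.csv` / `cam.csv` (plus
#'   metadata sidecars) are written there.
#' @return List with elements `reference` and `camera` (both trajectories).
#' @export
make_trial_pair <- function(spec, script, d = degradation_spec(),
                            seed = d$seed, participant = "synthetic",
                            dir = NULL) {
  d$seed <- as.integer(seed)
  ref <- generate_trajectory(spec, script, participant = participant)
  cam <- degrade(ref, d)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_trajectory(ref, file.path(dir, "ref.csv"))
    write_trajectory(cam, file.path(dir, "cam.csv"))
  }
  list(reference = ref, camera = cam)
}
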
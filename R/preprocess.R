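#' Clip two trajectories to their co-tracked time span
#'
#' Each tracking system starts and stops on its own schedule; comparisons are
#' only meaningful over the span seen by both. Both outputs are restricted to
#' `[max(starts), min(ends)]`.
#'
#' @param a,b Trajectories.
#' @return List of the two clipped trajectories, in input order.
#' @export
clip_to_overlap <- function(a, b) {
  lo <- max(a$time[1], b$time[1])
  hi <- min(a$time[length(a$time)], b$time[length(b$time)])
  if (lo >= hi) stop("trajectories have no overlapping time span", call. = FALSE)
  clip1 <- function(tr) {
    keep <- tr$time >= lo & tr$time <= hi
    trajectory(tr$time[keep], tr$positions[keep, , drop = FALSE],
               system = tr$system, task = tr$task, hand = tr$hand,
               participant = tr$participant)
  }
  list(clip1(a), clip1(b))
}

#' Resample a trajectory onto target timestamps
#'
#' Linear interpolation of every signal onto `target_time`; used to bring the
#' nonuniformly sampled camera stream onto the reference system's uniform time
#' base. No extrapolation: all targets must lie within the trajectory's span.
#'
#' @param traj A trajectory.
#' @param target_time Numeric vector of timestamps (s), strictly increasing.
#' @return Trajectory sampled at `target_time`.
#' @export
resample_to <- function(traj, target_time) {
  rng <- range(traj$time)
  if (any(target_time < rng[1]) || any(target_time > rng[2]))
    stop("target timestamps fall outside the trajectory's span; ",
         "extrapolation is not performed", call. = FALSE)
  pos <- apply(traj$positions, 2, function(col)
    stats::approx(traj$time, col, xout = target_time)$y)
  if (length(target_time) == 1L) pos <- matrix(pos, nrow = 1L)
  colnames(pos) <- colnames(traj$positions)
  trajectory(target_time, pos, system = traj$system, task = traj$task,
             hand = traj$hand, participant = traj$participant)
}

#' Build an analysis-ready trial pair
#'
#' Runs the full preprocessing chain on two raw single-system recordings:
#' clip to the co-tracked span, resample the camera stream onto the reference
#' timestamps, optionally drop the thumb-CMC columns (57-signal trials with a
#' misplaced CMC marker), and translationally align coordinate frames via
#' [align_coordinates()].
#'
#' @param ref Reference-system trajectory (uniformly sampled).
#' @param cam Camera-system trajectory (possibly nonuniform).
#' @param drop_cmc Drop the three thumb-CMC signals from both systems.
#' @param align Apply the index-MCP translational alignment (default `TRUE`).
#' @return Object of class `trial_pair`: common `time`, `ref` and `cam`
#'   position matrices, the applied `offset` (mm, x/y/z), and trial metadata.
#' @export
preprocess_pair <- function(ref, cam, drop_cmc = FALSE, align = TRUE) {
  clipped <- clip_to_overlap(ref, cam)
  ref <- clipped[[1]]
  cam <- clipped[[2]]
  # discrete clipping keeps samples, not the continuous span: drop reference
  # timestamps that precede/follow the camera's retained samples so the
  # resampler never extrapolates
  inside <- ref$time >= cam$time[1] & ref$time <= cam$time[length(cam$time)]
  if (!any(inside)) stop("no reference samples inside the camera span", call. = FALSE)
  if (!all(inside))
    ref <- trajectory(ref$time[inside], ref$positions[inside, , drop = FALSE],
                      system = ref$system, task = ref$task, hand = ref$hand,
                      participant = ref$participant)
  cam <- resample_to(cam, ref$time)
  keep <- colnames(ref$positions)
  if (drop_cmc) keep <- setdiff(keep, cmc_signal_names())
  pair <- structure(
    list(time = ref$time,
         ref = ref$positions[, keep, drop = FALSE],
         cam = cam$positions[, keep, drop = FALSE],
         offset = c(x = 0, y = 0, z = 0),
         n_signals = length(keep),
         task = ref$task, hand = ref$hand, participant = ref$participant),
    class = "trial_pair")
  if (align) align_coordinates(pair) else pair
}

#' Translational coordinate alignment of a trial pair
#'
#' Adds one constant (x, y, z) vector to every camera-system signal so that
#' the camera's index-MCP position equals the reference's at the first common
#' sample, compensating constant calibration offsets between the two devices'
#' coordinate frames. Rotation is not touched. The applied offset accumulates
#' in `pair$offset`; the operation is idempotent.
#'
#' @param pair A `trial_pair`.
#' @return The aligned `trial_pair`.
#' @export
align_coordinates <- function(pair) {
  stopifnot(inherits(pair, "trial_pair"))
  nm <- colnames(pair$ref)
  ci <- landmark_cols("index_mcp", nm)
  off <- pair$ref[1, ci] - pair$cam[1, ci]
  for (ax in 1:3) {
    cols <- seq(ax, ncol(pair$cam), by = 3)
    pair$cam[, cols] <- pair$cam[, cols] + off[ax]
  }
  pair$offset <- pair$offset + stats::setNames(as.numeric(off), c("x", "y", "z"))
  pair
}

#' @export
print.trial_pair <- function(x, ...) {
  cat(sprintf("<trial_pair> task=%s hand=%s participant=%s\n",
              x$task, x$hand, x$participant))
  cat(sprintf("  %d common samples, %d signals, alignment offset (%.2f, %.2f, %.2f) mm\n",
              length(x$time), x$n_signals, x$offset[1], x$offset[2], x$offset[3]))
  invisible(x)
}
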
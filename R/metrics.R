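# Conventional agreement metrics between two tracking systems on a trial pair:
# per-signal Pearson correlations and MAEs with their averages, task-specific
# inter-fingertip distance correlations, finger segment-length errors at a
# mid-trial frame, and the static/dynamic trial parameters.

# Pearson r for matched columns; constant columns in either system are
# flagged undefined (NA) rather than biasing the average
paired_pearson <- function(a, b) {
  vapply(seq_len(ncol(a)), function(i) {
    if (stats::sd(a[, i]) == 0 || stats::sd(b[, i]) == 0) NA_real_
    else stats::cor(a[, i], b[, i])
  }, numeric(1))
}

#' Per-signal correlations and their average
#'
#' Pearson correlation of each camera signal against its reference
#' counterpart over the matched samples; the trial-level summary is the
#' arithmetic mean over signals. Constant (zero-variance) signals have no
#' defined correlation: they are excluded from the mean and counted.
#'
#' @param pair A `trial_pair`.
#' @return List: `corr_i` (named per-signal vector, `NA` where undefined),
#'   `corr_signal` (mean over defined signals), `n_undefined`.
#' @export
signal_correlations <- function(pair) {
  stopifnot(inherits(pair, "trial_pair"))
  if (length(pair$time) < 3) stop("need at least 3 samples", call. = FALSE)
  r <- paired_pearson(pair$ref, pair$cam)
  names(r) <- colnames(pair$ref)
  list(corr_i = r,
       corr_signal = mean(r, na.rm = TRUE),
       n_undefined = sum(is.na(r)))
}

#' Per-signal mean absolute errors and their average
#'
#' `MAE_i` is the time-average of `|camera_i(t) - reference_i(t)|` (mm);
#' `mae_avg` averages over signals.
#'
#' @param pair A `trial_pair`.
#' @return List: `mae_i` (named vector, mm), `mae_avg` (mm).
#' @export
signal_mae <- function(pair) {
  stopifnot(inherits(pair, "trial_pair"))
  mae <- colMeans(abs(pair$cam - pair$ref))
  list(mae_i = mae, mae_avg = mean(mae))
}

# task-specific digit-tip pairings: thumb-to-each-tip for Kapandji,
# neighbouring tips for abduction/adduction
fingertip_pairs <- function(task) {
  switch(task,
    kapandji = list(TI = c("thumb_tip", "index_tip"),
                    TM = c("thumb_tip", "middle_tip"),
                    TR = c("thumb_tip", "ring_tip"),
                    TP = c("thumb_tip", "pinky_tip")),
    abd_add = list(TI = c("thumb_tip", "index_tip"),
                   IM = c("index_tip", "middle_tip"),
                   MR = c("middle_tip", "ring_tip"),
                   RP = c("ring_tip", "pinky_tip")),
    stop("unknown task '", task, "'", call. = FALSE))
}

#' Per-landmark 3D position error
#'
#' Complement to the per-axis [signal_mae()]: the time-averaged Euclidean
#' distance (mm) between each landmark's camera and reference positions.
#' Reported separately because averaging per-axis absolute errors and
#' averaging 3D error norms answer subtly different questions.
#'
#' @param pair A `trial_pair`.
#' @return List: `mae_landmark` (named per-landmark vector, mm) and
#'   `mae_landmark_avg`.
#' @export
landmark_mae_3d <- function(pair) {
  stopifnot(inherits(pair, "trial_pair"))
  nm <- colnames(pair$ref)
  lms <- unique(sub("_[xyz]$", "", nm))
  err <- vapply(lms, function(l) {
    ci <- landmark_cols(l, nm)
    mean(row_norms(pair$cam[, ci, drop = FALSE] - pair$ref[, ci, drop = FALSE]))
  }, numeric(1))
  list(mae_landmark = err, mae_landmark_avg = mean(err))
}

#' Task-specific inter-fingertip distance time series
#'
#' Reduces the 60-signal space to 4 functionally relevant distances: for the
#' Kapandji task, the thumb tip to each of the four fingertips; for
#' abduction/adduction, the distances between neighbouring digit tips
#' (thumb-index, index-middle, middle-ring, ring-pinky).
#'
#' @param x A `hand_trajectory`, a `trial_pair` position matrix, or a matrix
#'   with canonical signal columns.
#' @param task `"kapandji"` or `"abd_add"`.
#' @return m x 4 matrix of Euclidean distances (mm), columns named by digit
#'   pair.
#' @export
fingertip_distances <- function(x, task) {
  pos <- if (inherits(x, "hand_trajectory")) x$positions else as.matrix(x)
  pairs <- fingertip_pairs(task)
  out <- sapply(pairs, function(p)
    row_norms(landmark_track(pos, p[1]) - landmark_track(pos, p[2])))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(pairs)))
  out
}

#' Correlations of inter-fingertip distances
#'
#' Pearson correlation of each of the four task-specific fingertip distance
#' series between camera and reference, with the same degenerate-signal
#' handling as [signal_correlations()].
#'
#' @param pair A `trial_pair`.
#' @param task Task; defaults to the pair's metadata.
#' @return List: `corr_fingertip` (named length-4 vector), `n_undefined`.
#' @export
fingertip_correlations <- function(pair, task = pair$task) {
  stopifnot(inherits(pair, "trial_pair"))
  dr <- fingertip_distances(pair$ref, task)
  dc <- fingertip_distances(pair$cam, task)
  r <- paired_pearson(dr, dc)
  names(r) <- colnames(dr)
  list(corr_fingertip = r, n_undefined = sum(is.na(r)))
}

#' Finger segment lengths at a single frame
#'
#' Proximal (MCP-PIP), middle (PIP-DIP) and distal (DIP-tip) phalanx lengths
#' of the index, middle, ring and pinky fingers — 12 lengths — measured at one
#' frame (default: the middle of the trial). The thumb is excluded (its MCP is
#' not tracked).
#'
#' @param x Trajectory or canonical position matrix.
#' @param frame Frame index; default `floor(m / 2)` (at least 1).
#' @return Named numeric vector of 12 lengths (mm), names
#'   `<finger>_<proximal|middle|distal>`.
#' @export
segment_lengths <- function(x, frame = NULL) {
  pos <- if (inherits(x, "hand_trajectory")) x$positions else as.matrix(x)
  m <- nrow(pos)
  if (is.null(frame)) frame <- max(1L, m %/% 2L)
  if (frame < 1 || frame > m) stop("frame index out of range", call. = FALSE)
  nm <- colnames(pos)
  out <- numeric(0)
  for (f in finger_names()) {
    pts <- sapply(c("mcp", "pip", "dip", "tip"), function(j)
      pos[frame, landmark_cols(paste0(f, "_", j), nm)])
    seg <- sqrt(colSums((pts[, 2:4] - pts[, 1:3])^2))
    names(seg) <- paste0(f, "_", c("proximal", "middle", "distal"))
    out <- c(out, seg)
  }
  out
}

#' Segment-length errors between the two systems
#'
#' Camera-minus-reference phalanx length differences at the mid-trial frame.
#' Absolute errors quantify hand-model accuracy; signed errors expose
#' systematic under- or over-estimation (negative = camera underestimates).
#'
#' @param pair A `trial_pair`.
#' @param frame Frame index; default mid-trial.
#' @return List: `absolute` and `signed` named length-12 vectors (mm), and
#'   `frame` used.
#' @export
segment_length_errors <- function(pair, frame = NULL) {
  stopifnot(inherits(pair, "trial_pair"))
  if (is.null(frame)) frame <- max(1L, length(pair$time) %/% 2L)
  lr <- segment_lengths(pair$ref, frame)
  lc <- segment_lengths(pair$cam, frame)
  list(absolute = abs(lc - lr), signed = lc - lr, frame = frame)
}

#' Dynamic trial parameters
#'
#' Mean wrist height above the table plane (y = 0) over the trial, and the
#' task speed: the mean finite-difference speed of the thumb tip (Kapandji —
#' the digit doing the work) or the index fingertip (abduction/adduction).
#'
#' @param traj A `hand_trajectory`.
#' @param task Task; defaults to the trajectory's metadata.
#' @return List: `wrist_height_mm`, `speed_mm_s`, `speed_landmark`.
#' @export
trial_dynamics <- function(traj, task = traj$task) {
  stopifnot(inherits(traj, "hand_trajectory"))
  if (length(traj$time) < 2) stop("need at least 2 samples for speed", call. = FALSE)
  lm <- switch(task, kapandji = "thumb_tip", abd_add = "index_tip",
               stop("unknown task '", task, "'", call. = FALSE))
  tip <- landmark_track(traj$positions, lm)
  step <- row_norms(diff(tip))
  speed <- mean(step / diff(traj$time))
  wrist_y <- traj$positions[, landmark_cols("wrist", colnames(traj$positions))[2]]
  list(wrist_height_mm = mean(wrist_y), speed_mm_s = speed, speed_landmark = lm)
}

#' Static hand size from a flat pose
#'
#' Distance between the wrist and middle-MCP landmarks at the first frame,
#' where the protocol has the hand flat on the table.
#'
#' @param traj A `hand_trajectory` whose first frame is a flat pose.
#' @return Hand size (mm).
#' @export
hand_size_from <- function(traj) {
  stopifnot(inherits(traj, "hand_trajectory"))
  nm <- colnames(traj$positions)
  w <- traj$positions[1, landmark_cols("wrist", nm)]
  m <- traj$positions[1, landmark_cols("middle_mcp", nm)]
  sqrt(sum((w - m)^2))
}

#' Full conventional accuracy report for one trial pair
#'
#' Bundles every conventional metric for a preprocessed `trial_pair`.
#'
#' @param pair A `trial_pair`.
#' @param task Task; defaults to the pair's metadata.
#' @return Object of class `accuracy_report`.
#' @export
accuracy_report <- function(pair, task = pair$task) {
  sc <- signal_correlations(pair)
  sm <- signal_mae(pair)
  fc <- fingertip_correlations(pair, task)
  se <- segment_length_errors(pair)
  ref_traj <- trajectory(pair$time, pair$ref, system = "reference",
                         task = task, hand = pair$hand,
                         participant = pair$participant)
  dyn <- trial_dynamics(ref_traj, task)
  structure(
    list(task = task, hand = pair$hand, participant = pair$participant,
         n_signals = pair$n_signals,
         corr_i = sc$corr_i, corr_signal = sc$corr_signal,
         n_undefined = sc$n_undefined,
         mae_i = sm$mae_i, mae_avg = sm$mae_avg,
         corr_fingertip = fc$corr_fingertip,
         segment_errors = se$absolute, segment_errors_signed = se$signed,
         wrist_height_mm = dyn$wrist_height_mm, speed_mm_s = dyn$speed_mm_s,
         alignment_offset = pair$offset),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> task=%s hand=%s participant=%s (%d signals)\n",
              x$task, x$hand, x$participant, x$n_signals))
  cat(sprintf("  corr_signal = %.4f (%d undefined), mae_avg = %.3f mm\n",
              x$corr_signal, x$n_undefined, x$mae_avg))
  cat("  corr_fingertip:",
      paste(sprintf("%s=%.3f", names(x$corr_fingertip), x$corr_fingertip),
            collapse = " "), "\n")
  cat(sprintf("  mean |segment error| = %.3f mm; wrist height %.1f mm; speed %.1f mm/s\n",
              mean(x$segment_errors), x$wrist_height_mm, x$speed_mm_s))
  invisible(x)
}

#' Serialize an accuracy report
#'
#' @param report An `accuracy_report`.
#' @param path Output path; `.json` writes nested JSON, anything else a flat
#'   one-row CSV.
#' @return `path`, invisibly.
#' @export
write_accuracy_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    flat <- c(list(task = report$task, hand = report$hand,
                   participant = report$participant,
                   n_signals = report$n_signals,
                   corr_signal = report$corr_signal,
                   mae_avg = report$mae_avg,
                   wrist_height_mm = report$wrist_height_mm,
                   speed_mm_s = report$speed_mm_s),
              as.list(report$corr_fingertip),
              as.list(stats::setNames(report$segment_errors,
                                      paste0("err_", names(report$segment_errors)))))
    utils::write.csv(as.data.frame(flat), path, row.names = FALSE)
  }
  invisible(path)
}
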
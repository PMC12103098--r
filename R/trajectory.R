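#' Construct a trajectory
#'
#' A trajectory is one tracking system's recording of a trial: an m-vector of
#' strictly increasing timestamps (s) and an m x n matrix of landmark
#' positions (mm) with canonical `<landmark>_<axis>` column names (n = 60, or
#' 57 for trials where the thumb CMC landmark is unusable).
#'
#' @param time Numeric vector of timestamps (s), strictly increasing.
#' @param positions Numeric m x n matrix with canonical column names.
#' @param system System tag, e.g. `"reference"` or `"camera"`.
#' @param task Task identifier (`"kapandji"`, `"abd_add"`, or `NA`).
#' @param hand `"right"`, `"left"`, or `NA`.
#' @param participant Participant label.
#' @return Object of class `hand_trajectory`.
#' @export
trajectory <- function(time, positions, system = "reference",
                       task = NA_character_, hand = NA_character_,
                       participant = NA_character_) {
  time <- as.numeric(time)
  positions <- as.matrix(positions)
  if (length(time) != nrow(positions))
    stop("time and positions disagree on the number of samples", call. = FALSE)
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (anyNA(positions))
    stop("positions contain missing values", call. = FALSE)
  full <- signal_names()
  ok_full <- identical(colnames(positions), full)
  ok_57 <- identical(colnames(positions), setdiff(full, cmc_signal_names()))
  if (!ok_full && !ok_57)
    stop("positions must carry the 60 canonical signal columns ",
         "(or the 57-signal variant without thumb CMC)", call. = FALSE)
  structure(
    list(time = time, positions = positions, system = system,
         task = task, hand = hand, participant = participant),
    class = "hand_trajectory")
}

#' @export
print.hand_trajectory <- function(x, ...) {
  cat(sprintf("<hand_trajectory> %s | task=%s hand=%s participant=%s\n",
              x$system, x$task, x$hand, x$participant))
  cat(sprintf("  %d samples over %.2f s, %d signals\n",
              length(x$time), diff(range(x$time)), ncol(x$positions)))
  invisible(x)
}

n_signals <- function(traj) ncol(traj$positions)

#' Read / write trajectory files
#'
#' The on-disk format is plain delimited text: a `t_s` column followed by the
#' canonical signal columns, one row per sample, with a JSON metadata sidecar
#' (`<file>.meta.json`) recording system, task, hand and participant.
#'
#' @param path CSV file path.
#' @param traj A `hand_trajectory`.
#' @return `read_trajectory()` returns a `hand_trajectory`;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t_s = traj$time, traj$positions, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(system = traj$system, task = traj$task, hand = traj$hand,
               participant = traj$participant)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "t_s") stop("first column must be t_s", call. = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  pick <- function(k) if (!is.null(meta[[k]])) meta[[k]] else NA_character_
  trajectory(df$t_s, as.matrix(df[, -1, drop = FALSE]),
             system = if (!is.null(meta$system)) meta$system else "unknown",
             task = pick("task"), hand = pick("hand"),
             participant = pick("participant"))
}
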
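#' Canonical hand landmark set
#'
#' The pipeline tracks 20 landmarks per hand: the wrist; three thumb landmarks
#' (CMC, IP, tip — the thumb MCP is not tracked); and MCP, PIP, DIP and tip for
#' each of the index, middle, ring and pinky fingers. Each landmark contributes
#' an x, y and z position signal, for 60 signals per trial. All positions are
#' in millimetres; y is height above the table plane (y = 0).
#'
#' @return Character vector of the 20 landmark names in canonical order.
#' @export
#' @examples
#' hand_landmarks()
hand_landmarks <- function() {
  c("wrist",
    "thumb_cmc", "thumb_ip", "thumb_tip",
    paste0(rep(c("index", "middle", "ring", "pinky"), each = 4),
           "_", c("mcp", "pip", "dip", "tip")))
}

#' Canonical signal (column) names
#'
#' @param landmarks Landmark names; defaults to the full canonical set.
#' @return Character vector of `<landmark>_<axis>` column names, x/y/z per
#'   landmark, in canonical landmark order.
#' @export
signal_names <- function(landmarks = hand_landmarks()) {
  as.vector(t(outer(landmarks, c("x", "y", "z"), paste, sep = "_")))
}

#' @rdname hand_landmarks
#' @export
finger_names <- function() c("index", "middle", "ring", "pinky")

# columns (x,y,z) of one landmark within a canonical position matrix
landmark_cols <- function(landmark, names) {
  idx <- match(paste0(landmark, "_", c("x", "y", "z")), names)
  if (anyNA(idx)) stop("landmark '", landmark, "' not present", call. = FALSE)
  idx
}

# m x 3 position track of one landmark
landmark_track <- function(pos, landmark) {
  pos[, landmark_cols(landmark, colnames(pos)), drop = FALSE]
}

# the three thumb CMC columns, used for the 57-signal trial variant
cmc_signal_names <- function() paste0("thumb_cmc_", c("x", "y", "z"))
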
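# Forward-kinematic synthetic hand-motion generator.
#
# Geometry lives in a "hand frame": wrist at the origin, palm in the y = 0
# plane (parallel to the table), fingers pointing along +z, x across the palm.
# The generated hand rides 150 mm above the device origin plus a slow
# deterministic postural sway; both are rigid translations, so inter-landmark
# geometry (segment lengths, fingertip contacts) is unaffected by them.

HAND_HEIGHT_MM <- 150          # palm height above the device plane
KAPANDJI_CONTACT_TOL_MM <- 5   # a "touch" = thumb tip within this of a fingertip
THUMB_REACH_TARGET <- 0.82     # touch radius as a fraction of full thumb length
FLEXION_COUPLING <- c(1, 0.8, 0.5)  # MCP : PIP : DIP flexion ratio

# static layout of the four finger MCPs and the thumb CMC (right-hand template)
hand_layout <- function(spec) {
  dx <- c(-0.375, -0.125, 0.125, 0.375) * spec$palm_width
  rad <- c(0.98, 1.0, 0.97, 0.88) * spec$hand_size
  dz <- sqrt(rad^2 - dx^2)
  mcp <- cbind(x = dx, y = 0, z = dz)
  rownames(mcp) <- finger_names()
  cmc <- c(-0.55 * spec$palm_width, 0, 0.30 * spec$hand_size)
  thumb_dir <- c(-0.5, -0.15, 0.85)
  thumb_dir <- thumb_dir / sqrt(sum(thumb_dir^2))
  list(mcp = mcp, alpha0 = stats::setNames(atan2(dx, dz), finger_names()),
       cmc = cmc, thumb_rest_dir = thumb_dir)
}

# finger chain for per-frame flexion theta (rad, vector) and splay alpha (rad,
# vector) from a fixed MCP; returns list of m x 3 matrices pip/dip/tip
finger_chain <- function(mcp, alpha, theta, lp, lm, ld) {
  ux <- sin(alpha); uz <- cos(alpha)
  cum <- cumsum(FLEXION_COUPLING)
  seg <- function(base, phi, len) {
    cbind(base[, 1] + len * cos(phi) * ux,
          base[, 2] - len * sin(phi),
          base[, 3] + len * cos(phi) * uz)
  }
  m <- length(theta)
  mcp_m <- matrix(mcp, m, 3, byrow = TRUE)
  pip <- seg(mcp_m, cum[1] * theta, lp)
  dip <- seg(pip, cum[2] * theta, lm)
  tip <- seg(dip, cum[3] * theta, ld)
  list(mcp = mcp_m, pip = pip, dip = dip, tip = tip)
}

# two-link thumb inverse kinematics: place the tip at each row of `target`
# (hand-frame), bending at the IP landmark; CMC->IP = metacarpal + proximal,
# IP->tip = distal. Targets outside the reach annulus are clamped radially.
thumb_chain <- function(cmc, target, len_a, len_b) {
  d <- sweep(target, 2, cmc)
  r <- sqrt(rowSums(d^2))
  r <- pmin(pmax(r, abs(len_a - len_b) + 1), len_a + len_b - 1)
  dhat <- d / r
  # bend-plane normal: component of +y orthogonal to the reach direction
  p <- cbind(-dhat[, 1] * dhat[, 2], 1 - dhat[, 2]^2, -dhat[, 3] * dhat[, 2])
  pn <- sqrt(rowSums(p^2))
  bad <- pn < 1e-9
  if (any(bad)) { p[bad, ] <- rep(c(1, 0, 0), each = sum(bad)); pn[bad] <- 1 }
  p <- p / pn
  cosb <- (len_a^2 + r^2 - len_b^2) / (2 * len_a * r)
  sinb <- sqrt(pmax(0, 1 - cosb^2))
  ip <- sweep(len_a * (cosb * dhat + sinb * p), 2, cmc, "+")
  tip <- sweep(r * dhat, 2, cmc, "+")
  list(ip = ip, tip = tip)
}

# hand-frame fingertip position for a single flexion angle (scalar helper)
flexed_tip <- function(mcp, alpha, theta, lp, lm, ld) {
  finger_chain(mcp, alpha, theta, lp, lm, ld)$tip[1, ]
}

# flexion angle bringing finger f's tip to the thumb's comfortable touch
# radius; deterministic grid search, errors when the touch is unreachable
solve_touch_flexion <- function(layout, spec, finger, theta_max) {
  reach <- sum(spec$thumb[c("metacarpal", "proximal")]) + spec$thumb["distal"]
  r_star <- THUMB_REACH_TARGET * reach
  grid <- seq(0, theta_max, length.out = 481)
  f <- finger
  dist <- vapply(grid, function(th) {
    tip <- flexed_tip(layout$mcp[f, ], layout$alpha0[[f]], th,
                      spec$proximal[[f]], spec$middle[[f]], spec$distal[[f]])
    sqrt(sum((tip - layout$cmc)^2))
  }, numeric(1))
  best <- which.min(abs(dist - r_star))
  len_a <- sum(spec$thumb[c("metacarpal", "proximal")])
  len_b <- spec$thumb[["distal"]]
  if (dist[best] < abs(len_a - len_b) + 2 || dist[best] > len_a + len_b - 2)
    stop("kapandji touch of the ", f,
         " fingertip is unreachable for this hand geometry", call. = FALSE)
  grid[best]
}

# cosine-eased piecewise interpolation through 3D waypoints
waypoint_path <- function(t, wp_t, wp) {
  i <- pmin(pmax(findInterval(t, wp_t), 1L), length(wp_t) - 1L)
  u <- (t - wp_t[i]) / (wp_t[i + 1L] - wp_t[i])
  s <- (1 - cos(pi * pmin(pmax(u, 0), 1))) / 2
  wp[i, ] + s * (wp[i + 1L, ] - wp[i, ])
}

# slow deterministic postural sway (mm), zero amplitude -> exactly static;
# rank one (a single shared oscillation with per-axis weights): postural
# drift moves the arm as a unit, it is not three independent processes
postural_sway <- function(t, amp) {
  s <- sin(2 * pi * 0.21 * t + 0.8)
  amp * cbind(1.0 * s, 0.5 * s, 0.8 * s)
}

#' Generate a synthetic hand-task trajectory
#'
#' Produces a uniformly sampled, noise-free trajectory of all 20 landmarks for
#' one trial of the requested task, from a parametric forward-kinematic hand
#' model. Finger flexion uses a fixed 1 : 0.8 : 0.5 MCP/PIP/DIP coupling; the
#' thumb is a two-link chain driven by closed-form inverse kinematics, so in
#' the Kapandji task its tip meets each fingertip exactly (well within the
#' 5 mm contact tolerance), once, in index-to-pinky order. In the
#' abduction/adduction task the extended fingers splay periodically. The palm
#' stays parallel to the table; segment lengths are conserved to numerical
#' precision in every frame.
#'
#' @param spec A [hand_spec()].
#' @param script A [task_script()].
#' @param participant Participant label stored in the metadata.
#' @param system System tag for the output (default `"reference"`).
#' @return A [trajectory()] with 60 signals.
#' @export
#' @examples
#' traj <- generate_trajectory(hand_spec(), task_script("abd_add", duration = 2))
#' traj
generate_trajectory <- function(spec, script, participant = "synthetic",
                                system = "reference") {
  stopifnot(inherits(spec, "hand_spec"), inherits(script, "task_script"))
  layout <- hand_layout(spec)
  t <- seq(0, script$duration, by = 1 / script$rate)
  m <- length(t)
  scale <- script$amplitude_scale
  fingers <- finger_names()

  # per-finger splay and flexion profiles
  alpha <- sapply(fingers, function(f) rep(layout$alpha0[[f]], m))
  theta <- matrix(0, m, 4, dimnames = list(NULL, fingers))
  if (script$task == "abd_add" && scale > 0) {
    gain <- c(index = -1, middle = -1 / 3, ring = 1 / 3, pinky = 1)
    osc <- sin(2 * pi * script$cycles * t / script$duration)
    for (f in fingers)
      alpha[, f] <- alpha[, f] + gain[[f]] * script$abduction_amp * scale * osc
  }
  touch_t <- NULL
  if (script$task == "kapandji" && scale > 0) {
    frac <- c(0.18, 0.38, 0.58, 0.78)
    touch_t <- round(frac * script$duration * script$rate) / script$rate
    w <- 0.12 * script$duration
    # fingers share a common flexion envelope (grasp-like synergy) with an
    # individual bump carrying each finger to its touch posture; the shared
    # component mirrors the strong inter-finger coupling of real hand motion
    env <- 0.6 * sin(pi * t / script$duration)^2
    for (k in seq_along(fingers)) {
      f <- fingers[k]
      th_touch <- solve_touch_flexion(layout, spec, f, scale * script$flexion_max)
      bump <- ifelse(abs(t - touch_t[k]) <= w,
                     cos(pi * (t - touch_t[k]) / (2 * w))^2, 0)
      theta[, f] <- th_touch * pmax(bump, env)
    }
  }

  chains <- lapply(fingers, function(f)
    finger_chain(layout$mcp[f, ], alpha[, f], theta[, f],
                 spec$proximal[[f]], spec$middle[[f]], spec$distal[[f]]))
  names(chains) <- fingers

  # thumb target path (hand frame)
  len_a <- sum(spec$thumb[c("metacarpal", "proximal")])
  len_b <- spec$thumb[["distal"]]
  rest <- layout$cmc + 0.88 * (len_a + len_b) * layout$thumb_rest_dir
  if (script$task == "kapandji" && scale > 0) {
    idx <- as.integer(round(touch_t * script$rate)) + 1L
    wp <- rbind(rest, t(sapply(seq_along(fingers), function(k)
      chains[[fingers[k]]]$tip[idx[k], ])), rest)
    target <- waypoint_path(t, c(0, touch_t, script$duration), wp)
  } else if (script$task == "abd_add" && scale > 0) {
    phi <- -1.5 * script$abduction_amp * scale *
      sin(2 * pi * script$cycles * t / script$duration)
    d0 <- layout$thumb_rest_dir
    dir <- cbind(d0[1] * cos(phi) + d0[3] * sin(phi),
                 rep(d0[2], m),
                 -d0[1] * sin(phi) + d0[3] * cos(phi))
    target <- sweep(0.88 * (len_a + len_b) * dir, 2, layout$cmc, "+")
  } else {
    target <- matrix(rest, m, 3, byrow = TRUE)
  }
  thumb <- thumb_chain(layout$cmc, target, len_a, len_b)

  # assemble canonical 60-column matrix, then lift into world coordinates
  pos <- matrix(0, m, 60, dimnames = list(NULL, signal_names()))
  put <- function(name, xyz) pos[, landmark_cols(name, colnames(pos))] <<- xyz
  put("wrist", matrix(0, m, 3))
  put("thumb_cmc", matrix(layout$cmc, m, 3, byrow = TRUE))
  put("thumb_ip", thumb$ip)
  put("thumb_tip", thumb$tip)
  for (f in fingers) {
    put(paste0(f, "_mcp"), chains[[f]]$mcp)
    put(paste0(f, "_pip"), chains[[f]]$pip)
    put(paste0(f, "_dip"), chains[[f]]$dip)
    put(paste0(f, "_tip"), chains[[f]]$tip)
  }
  sway <- postural_sway(t, script$sway_mm * scale)
  base <- c(0, HAND_HEIGHT_MM, 0)
  for (ax in 1:3) {
    cols <- seq(ax, 60, by = 3)
    pos[, cols] <- pos[, cols] + base[ax] + sway[, ax]
  }
  if (spec$hand == "left") pos[, seq(1, 60, by = 3)] <- -pos[, seq(1, 60, by = 3)]

  trajectory(t, pos, system = system, task = script$task, hand = spec$hand,
             participant = participant)
}
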
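# Ground-truth synthetic reach-to-grasp scenes: a parametric kinematic
# model of a single reach, a simulated real + virtual (mirror) camera pair,
# and projection into DeepLabCut-style two-view keypoint observations.

BODYPARTS <- c("hand_dorsum", "digit1", "digit2", "digit3", "digit4",
               "mcp2", "pellet")

rot_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, 3, byrow = TRUE)
}

#' Ground-truth mirror-scene geometry for simulation
#'
#' A real camera at the origin looking down +z and a virtual camera (the
#' mirror view after x-reflection) rotated about the vertical axis, both
#' sharing one intrinsic model. The pellet sits ~30 cm in front of the real
#' camera. The raw mirror image is stored unreflected
#' (`x_raw = image_width - x`), as a physical mirror produces it.
#'
#' @param camera A [camera_model()] (default: 1400 px focals on a
#'   2400 x 1024 sensor).
#' @param mirror_angle_deg Rotation of the virtual camera about the y axis
#'   (default -75 degrees).
#' @param pellet_origin Pellet position in the real-camera frame (mm).
#' @return Object of class `synthetic_scene`: `camera`, `R`, `t_mm`,
#'   `P_real`, `P_virtual`, `pellet_origin`, `mirror_flip`.
#' @export
synthetic_calibration <- function(camera = camera_model(1400, 1400, 1200, 512),
                                  mirror_angle_deg = -75,
                                  pellet_origin = c(0, 0, 300)) {
  R <- rot_y(mirror_angle_deg * pi / 180)
  t_mm <- as.numeric(pellet_origin - R %*% pellet_origin)
  structure(list(camera = camera, R = R, t_mm = t_mm,
                 P_real = camera$K %*% cbind(diag(3), 0),
                 P_virtual = camera$K %*% cbind(R, t_mm),
                 pellet_origin = pellet_origin, mirror_flip = TRUE),
            class = "synthetic_scene")
}

#' Parameters of the synthetic reach shape model
#'
#' The digit-2 tip advances along z with a smooth raised-cosine bump from
#' inside the box (z ~ -22 mm) to a single peak past the pellet
#' (`z_peak`), then retracts below the slot plane. Digit flexion holds at
#' its transport value, dips to a single minimum (maximum extension) at the
#' advance peak, rises steeply to a single maximum (the grasp), and
#' relaxes. Aperture opens with advance and closes after the peak; hand
#' orientation pronates with advance. Before movement onset the hand drifts
#' slowly backwards (withdrawal from the previous attempt), which makes the
#' onset of forward velocity a well-defined transition. All monotone-
#' segment properties hold exactly at zero noise, so every event frame is
#' known analytically.
#'
#' @param n_pre,n_rise,n_fall,n_post Frame counts of the four phases.
#' @param z_start,z_peak,z_retract Digit-2 z landmarks (mm, pellet frame).
#' @param drift_mm_per_frame,n_drift Pre-onset backward drift.
#' @param flex_rest,flex_min,flex_max,flex_relax Flexion landmarks (deg).
#' @param n_extend,n_grasp,n_relax Frame counts of the flexion segments.
#' @param aperture_rest,aperture_peak,aperture_close Aperture landmarks (mm).
#' @param orient_rest,orient_peak Orientation landmarks (deg).
#' @param y_rest,y_lift Hand height landmarks (mm).
#' @param x_offset Lateral offset of the reach axis from the pellet (mm).
#' @param seg_hand_mcp,seg_mcp_tip Hand-dorsum-to-MCP2 and MCP2-to-digit-tip
#'   segment lengths (mm).
#' @export
reach_params <- function(n_pre = 30, n_rise = 22, n_fall = 20, n_post = 20,
                         z_start = -22, z_peak = 8, z_retract = -18,
                         drift_mm_per_frame = 0.5, n_drift = 10,
                         flex_rest = 40, flex_min = 10, flex_max = 80,
                         flex_relax = 55,
                         n_extend = 8, n_grasp = 8, n_relax = 5,
                         aperture_rest = 6, aperture_peak = 12,
                         aperture_close = 5,
                         orient_rest = 30, orient_peak = 75,
                         y_rest = -5, y_lift = 3, x_offset = 1,
                         seg_hand_mcp = 6, seg_mcp_tip = 8) {
  as.list(environment())
}

# raised-cosine ramp from 0 to 1 over n steps, evaluated at s = 0..n
cos_ramp <- function(s, n) sin(pi * s / (2 * n))^2

# noiseless per-frame profiles of the shape model
reach_profiles <- function(p) {
  n_frames <- p$n_pre + p$n_rise + p$n_fall + p$n_post
  t <- seq_len(n_frames)
  peak <- p$n_pre + p$n_rise

  z <- numeric(n_frames)
  hold <- p$z_start + p$drift_mm_per_frame * p$n_drift
  z[t <= p$n_pre - p$n_drift] <- hold
  dr <- t > p$n_pre - p$n_drift & t <= p$n_pre
  z[dr] <- hold - p$drift_mm_per_frame * (t[dr] - (p$n_pre - p$n_drift))
  ri <- t > p$n_pre & t <= peak
  z[ri] <- p$z_start + (p$z_peak - p$z_start) * cos_ramp(t[ri] - p$n_pre, p$n_rise)
  fa <- t > peak & t <= peak + p$n_fall
  z[fa] <- p$z_peak + (p$z_retract - p$z_peak) * cos_ramp(t[fa] - peak, p$n_fall)
  z[t > peak + p$n_fall] <- p$z_retract

  prog <- pmax(0, pmin(1, (z - p$z_start) / (p$z_peak - p$z_start)))
  prog[t > peak] <- pmax(0, pmin(1, (z[t > peak] - p$z_start) / (p$z_peak - p$z_start)))
  y <- p$y_rest + (p$y_lift - p$y_rest) * prog
  theta <- p$orient_rest + (p$orient_peak - p$orient_rest) * prog
  theta[t > peak] <- p$orient_peak  # pronation holds through the grasp

  delta <- rep(p$flex_rest, n_frames)
  ex <- t > peak - p$n_extend & t <= peak
  delta[ex] <- p$flex_min + (p$flex_rest - p$flex_min) *
    cos_ramp(peak - t[ex], p$n_extend)
  gr <- t > peak & t <= peak + p$n_grasp
  delta[gr] <- p$flex_min + (p$flex_max - p$flex_min) *
    cos_ramp(t[gr] - peak, p$n_grasp)
  rl <- t > peak + p$n_grasp & t <= peak + p$n_grasp + p$n_relax
  delta[rl] <- p$flex_max - (p$flex_max - p$flex_relax) *
    cos_ramp(t[rl] - peak - p$n_grasp, p$n_relax)
  delta[t > peak + p$n_grasp + p$n_relax] <- p$flex_relax

  a <- p$aperture_rest + (p$aperture_peak - p$aperture_rest) * prog
  cl <- t > peak & t <= peak + p$n_grasp
  a[cl] <- p$aperture_peak + (p$aperture_close - p$aperture_peak) *
    cos_ramp(t[cl] - peak, p$n_grasp)
  a[t > peak + p$n_grasp] <- p$aperture_close

  data.frame(frame = t, z_digit2 = z, y = y, aperture = a,
             orientation = theta, flexion = delta)
}

# analytic event frames of the shape model
true_events_from_params <- function(p, slot_z = -15) {
  pr <- reach_profiles(p)
  peak <- as.integer(p$n_pre + p$n_rise)
  list(reach_start = as.integer(p$n_pre),
       slot_crossing = which(pr$z_digit2 > slot_z)[1],
       reach_end = peak,
       grasp_start = peak + 1L,
       grasp_end = as.integer(peak + p$n_grasp))
}

#' Generate one ground-truth synthetic reach trial
#'
#' Renders the shape model of [reach_params()] into 3D pellet-frame
#' trajectories for all tracked bodyparts, with optional i.i.d. Gaussian
#' per-frame jitter and a rigid per-trial offset. The digit-2 tip carries
#' the designed z profile; the MCP joint and hand dorsum hang behind it
#' along the hand axis so that the designed flexion angle is reproduced
#' exactly; digits 1 and 4 flank digit 2 so that the designed aperture and
#' orientation are reproduced exactly. The pellet is stationary at the
#' origin and never jittered.
#'
#' @param params A [reach_params()] list.
#' @param noise_amplitude Per-frame, per-coordinate Gaussian SD (mm).
#' @param endpoint_offset 3-vector rigid offset applied to every bodypart
#'   except the pellet (mm).
#' @param frame_rate Frames per second (default 300).
#' @return List: `traj` (a [trial_trajectories()]), `true_events`,
#'   `profiles` (noiseless per-frame shape values).
#' @export
generate_reach_trajectory <- function(params = reach_params(),
                                      noise_amplitude = 0,
                                      endpoint_offset = c(0, 0, 0),
                                      frame_rate = 300) {
  stopifnot(frame_rate > 0, noise_amplitude >= 0)
  pr <- reach_profiles(params)
  n <- nrow(pr)
  d2 <- cbind(params$x_offset, pr$y, pr$z_digit2)
  dirv <- cbind(0, -sin(pr$flexion * pi / 180), cos(pr$flexion * pi / 180))
  mcp2 <- d2 - params$seg_mcp_tip * dirv
  hand <- mcp2 - params$seg_hand_mcp * cbind(0, 0, rep(1, n))
  w <- cbind(cos(pr$orientation * pi / 180), sin(pr$orientation * pi / 180), 0)
  d1 <- d2 - (pr$aperture / 2) * w
  d4 <- d2 + (pr$aperture / 2) * w
  d3 <- d2 + (pr$aperture / 4) * w
  pos <- list(hand_dorsum = hand, digit1 = d1, digit2 = d2, digit3 = d3,
              digit4 = d4, mcp2 = mcp2, pellet = matrix(0, n, 3))
  for (b in setdiff(BODYPARTS, "pellet")) {
    pos[[b]] <- sweep(pos[[b]], 2, -endpoint_offset)
    if (noise_amplitude > 0)
      pos[[b]] <- pos[[b]] + matrix(rnorm(3 * n, sd = noise_amplitude), n, 3)
  }
  list(traj = trial_trajectories(pos, frame_rate = frame_rate),
       true_events = true_events_from_params(params),
       profiles = pr)
}

#' Project a 3D trial into two-view keypoint observations
#'
#' Maps pellet-frame trajectories into the real-camera frame, projects
#' through the real and virtual cameras, and emits DeepLabCut-style
#' observations with confidence values. Clean points draw confidence above
#' 0.97. Mislabeled points (independent per view at `mislabel_rate`) are
#' displaced 60-200 px in a random direction and draw confidence below
#' 0.97 (a mix of the 0.85-0.97 band and sub-0.85), so the validity rule
#' flags them. Occluded points (at `occlusion_rate` per frame/bodypart)
#' are omitted from one randomly chosen view. Raw mirror x is reflected
#' (`image_width - x`) as a physical mirror produces it.
#'
#' @param traj A [trial_trajectories()] in the pellet frame.
#' @param scene A [synthetic_calibration()].
#' @param mislabel_rate,occlusion_rate Fractions in \[0, 1\].
#' @param hand `"right"` or `"left"` (left scenes are reflected before
#'   rendering so analysis-side x negation round-trips).
#' @return Data frame: `frame`, `bodypart`, `view`, `x`, `y`,
#'   `confidence`, `true_mislabel`, `true_occluded`.
#' @export
project_to_views <- function(traj, scene = synthetic_calibration(),
                             mislabel_rate = 0, occlusion_rate = 0,
                             hand = "right") {
  stopifnot(mislabel_rate >= 0, mislabel_rate <= 1,
            occlusion_rate >= 0, occlusion_rate <= 1)
  w_px <- scene$camera$image_width
  rows <- vector("list", 2 * length(traj$positions))
  k <- 0
  for (b in names(traj$positions)) {
    X <- from_pellet_frame(traj$positions[[b]], scene$pellet_origin, hand)
    n <- nrow(X)
    occl <- runif(n) < occlusion_rate
    occl_view <- sample(c("direct", "mirror"), n, replace = TRUE)
    for (view in c("direct", "mirror")) {
      P <- if (view == "direct") scene$P_real else scene$P_virtual
      xy <- project_points(X, P)
      if (view == "mirror") xy[, 1] <- w_px - xy[, 1]
      mis <- runif(n) < mislabel_rate
      conf <- runif(n, 0.9705, 0.9999)
      if (any(mis)) {
        r <- runif(sum(mis), 60, 200)
        ang <- runif(sum(mis), 0, 2 * pi)
        xy[mis, 1] <- xy[mis, 1] + r * cos(ang)
        xy[mis, 2] <- xy[mis, 2] + r * sin(ang)
        conf[mis] <- runif(sum(mis), 0.5, 0.969)
      }
      drop <- occl & occl_view == view
      keep <- !drop
      k <- k + 1
      rows[[k]] <- data.frame(frame = which(keep), bodypart = b, view = view,
                              x = xy[keep, 1], y = xy[keep, 2],
                              confidence = conf[keep],
                              true_mislabel = mis[keep],
                              true_occluded = drop[keep])
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$bodypart, out$view, out$frame), , drop = FALSE]
}

#' Checkerboard-cube calibration correspondences
#'
#' Projects corner points of a calibration cube carrying 4 mm checkerboards
#' on its faces through the real and virtual cameras. Two faces of the cube
#' (a 5 x 5 corner grid each) are used per pose, and the cube is imaged at
#' several poses spread through the reaching workspace - as in a real
#' calibration session - which conditions the essential-matrix estimate far
#' better than a single pose.
#'
#' @param scene A [synthetic_calibration()].
#' @param n_points Number of correspondences (>= 8).
#' @param pixel_noise Gaussian pixel noise SD added to every coordinate.
#' @param square_mm Checker square side (default 4).
#' @return Data frame: `frame` (cube pose), `point_id`, `face`, `row`,
#'   `col`, `x_direct`, `y_direct`, `x_mirror` (raw, reflected), `y_mirror`.
#' @export
generate_checkerboard_correspondences <- function(scene = synthetic_calibration(),
                                                  n_points = 48,
                                                  pixel_noise = 0,
                                                  square_mm = 4) {
  if (n_points < 8) stop("at least 8 correspondences are required for essential-matrix estimation")
  g <- expand.grid(row = 0:4, col = 0:4)
  ctr <- scene$pellet_origin
  # face 1: plane normal ~x (cube side), grid in (y, z); face 2: normal ~y
  f1 <- cbind(-10, (g$row - 2) * square_mm, (g$col - 2) * square_mm)
  f2 <- cbind((g$row - 2) * square_mm, -10, (g$col - 2) * square_mm)
  poses <- rbind(c(0, 0, 0), c(80, 30, -60), c(-80, -30, 60),
                 c(120, -40, 90), c(-110, 40, -80), c(60, 45, 30))
  X <- NULL; face <- integer(0); grid <- NULL; pose_id <- integer(0)
  for (pz in seq_len(nrow(poses))) {
    Xp <- rbind(f1, f2)
    Xp <- sweep(Xp, 2, -(ctr + poses[pz, ]))
    ord <- order(rep(seq_len(nrow(g)), 2), rep(1:2, each = nrow(g)))
    X <- rbind(X, Xp[ord, , drop = FALSE])
    face <- c(face, rep(1:2, nrow(g)))
    grid <- rbind(grid, rbind(g, g)[ord, ])
    pose_id <- c(pose_id, rep(pz, 2 * nrow(g)))
  }
  # round-robin across poses so small n still spans the workspace
  rr <- order(rep(seq_len(2 * nrow(g)), nrow(poses)), pose_id)
  X <- X[rr, , drop = FALSE]; face <- face[rr]; grid <- grid[rr, ]
  pose_id <- pose_id[rr]
  n_points <- min(n_points, nrow(X))
  idx <- seq_len(n_points)
  xd <- project_points(X[idx, , drop = FALSE], scene$P_real)
  xm <- project_points(X[idx, , drop = FALSE], scene$P_virtual)
  xm[, 1] <- scene$camera$image_width - xm[, 1]
  if (pixel_noise > 0) {
    xd <- xd + matrix(rnorm(2 * n_points, sd = pixel_noise), n_points, 2)
    xm <- xm + matrix(rnorm(2 * n_points, sd = pixel_noise), n_points, 2)
  }
  out <- data.frame(frame = pose_id[idx], point_id = idx, face = face[idx],
                    row = grid$row[idx], col = grid$col[idx],
                    x_direct = xd[, 1], y_direct = xd[, 2],
                    x_mirror = xm[, 1], y_mirror = xm[, 2])
  attr(out, "X_true") <- X[idx, , drop = FALSE]
  out
}
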
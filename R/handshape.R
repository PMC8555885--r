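# Hand-shaping measures: grasp aperture, hand orientation, digit flexion,
# plus reach velocity and duration.

#' Grasp aperture
#'
#' Euclidean distance between the tips of the first and fourth digits, in mm.
#' Vectorized over frames.
#'
#' @param d1_tip,d4_tip n x 3 matrices (or 3-vectors) of digit-tip
#'   positions (mm).
#' @return Numeric vector of apertures (mm); `NA` where either tip is `NA`.
#' @export
aperture <- function(d1_tip, d4_tip) {
  d1 <- rbind(d1_tip); d4 <- rbind(d4_tip)
  unname(sqrt(rowSums((d4 - d1)^2)))
}

#' Hand orientation against horizontal in the direct camera view
#'
#' Angle of the undirected line joining the digit-1 and digit-4 tips
#' against horizontal, computed in the direct-view image plane with image y
#' measured upward, reported in \[0, 180) degrees. For left-handed reaches
#' x is negated first so pronation angles are comparable across hands.
#'
#' @param d1_xy,d4_xy n x 2 matrices of tip positions in the direct view
#'   (x right, y up).
#' @param hand `"right"` or `"left"`.
#' @return Orientation in degrees, `NA` where the tips coincide.
#' @export
hand_orientation <- function(d1_xy, d4_xy, hand = c("right", "left")) {
  hand <- match.arg(hand)
  d1 <- rbind(d1_xy); d4 <- rbind(d4_xy)
  v <- d4 - d1
  if (hand == "left") v[, 1] <- -v[, 1]
  theta <- unname(atan2(v[, 2], v[, 1]) * 180 / pi)
  theta <- theta %% 180
  theta[abs(v[, 1]) < .Machine$double.eps & abs(v[, 2]) < .Machine$double.eps] <- NA_real_
  theta
}

#' Digit-2 flexion angle at the MCP joint
#'
#' Angle between the hand axis (hand dorsum to second MCP joint) and the
#' digit axis (second MCP joint to digit-2 tip), in degrees:
#' 0 means the digit is collinear with the hand axis (fully extended);
#' larger values mean more flexion, up to 180.
#'
#' @param hand_dorsum,mcp2,d2_tip n x 3 matrices (mm).
#' @return Flexion in degrees, `NA` where either segment has zero length.
#' @export
digit_flexion <- function(hand_dorsum, mcp2, d2_tip) {
  u <- rbind(mcp2) - rbind(hand_dorsum)
  v <- rbind(d2_tip) - rbind(mcp2)
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  cosang <- rowSums(u * v) / (nu * nv)
  out <- unname(acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
  out[nu == 0 | nv == 0] <- NA_real_
  out
}

#' Reach velocity from the hand dorsum
#'
#' Euclidean distance of the hand dorsum between consecutive valid frames
#' divided by the interframe interval. Gaps (invalid frames in between)
#' yield no sample.
#'
#' @param hand_xyz frames x 3 matrix (mm).
#' @param valid Per-frame validity.
#' @param frame_rate Frames per second (default 300).
#' @return List: `speed` (mm/s, one value per consecutive valid frame pair,
#'   indexed by `frame` = the earlier frame) and `max_speed`.
#' @export
reach_velocity <- function(hand_xyz, valid = rep(TRUE, nrow(hand_xyz)),
                           frame_rate = 300) {
  f <- which(valid)
  consec <- which(diff(f) == 1L)
  if (!length(consec)) return(list(speed = numeric(0), frame = integer(0),
                                   max_speed = NA_real_))
  i <- f[consec]
  d <- sqrt(rowSums((hand_xyz[i + 1L, , drop = FALSE] -
                     hand_xyz[i, , drop = FALSE])^2))
  sp <- d * frame_rate
  list(speed = sp, frame = i, max_speed = max(sp))
}

#' Reach duration
#'
#' Number of frames between the hand first passing through the reaching
#' slot and reach end, divided by the frame rate.
#'
#' @param slot_crossing,reach_end Frame indices.
#' @param frame_rate Frames per second (default 300).
#' @return Duration in seconds.
#' @export
reach_duration <- function(slot_crossing, reach_end, frame_rate = 300) {
  if (any(reach_end < slot_crossing)) stop("reach_end precedes slot_crossing")
  (reach_end - slot_crossing) / frame_rate
}
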
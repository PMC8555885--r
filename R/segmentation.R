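# Frame-level reach/grasp event detection. A reach runs from the hand
# starting to move forward, through the slot crossing, to the onset of
# digit-2 retraction; the grasp runs from the onset of increasing digit-2
# flexion (after maximum extension) to maximum flexion.

#' Slot geometry in the pellet reference frame
#'
#' The reaching-slot plane expressed as a z-coordinate in the pellet frame.
#' With the pellet delivery rod 15 mm beyond the front of the slot, the slot
#' plane sits at z = -15 mm.
#'
#' @param slot_z z-coordinate of the slot plane (mm, pellet frame).
#' @export
slot_geometry <- function(slot_z = -15) {
  stopifnot(is.finite(slot_z))
  structure(list(slot_z = slot_z), class = "slot_geometry")
}

# centred 3-frame median filter (ends passed through unchanged)
median3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  y <- x
  for (i in 2:(n - 1)) y[i] <- median(x[(i - 1):(i + 1)])
  y
}

#' First frame with any digit tip outside the box
#'
#' @param digit_z frames x k matrix of digit-tip z-coordinates (pellet
#'   frame, mm), one column per digit.
#' @param valid frames x k logical matrix of point validity.
#' @param slot A [slot_geometry()].
#' @param from First frame to consider.
#' @return Frame index of the slot crossing, or `NA` if the digits never
#'   cross the slot plane.
#' @export
find_slot_crossing <- function(digit_z, valid, slot, from = 1L) {
  digit_z <- as.matrix(digit_z); valid <- as.matrix(valid)
  out <- rowSums(valid & digit_z > slot$slot_z, na.rm = TRUE) > 0
  out[seq_len(min(from - 1L, length(out)))] <- FALSE
  idx <- which(out)
  if (!length(idx)) NA_integer_ else idx[1]
}

#' Backtrack from the slot crossing to the start of forward hand motion
#'
#' Scans backwards in time from the slot crossing until the hand dorsum's
#' forward (z) velocity has been non-positive for `k` consecutive
#' valid-frame steps; the reach starts at the frame after that. If the
#' backtrack reaches the start of the series the first valid frame is
#' returned (hand already moving forward at series start).
#'
#' @param hand_z Per-frame hand-dorsum z (pellet frame, mm).
#' @param valid Per-frame validity of the hand-dorsum point.
#' @param slot_crossing Frame index from [find_slot_crossing()].
#' @param k Number of consecutive non-positive velocity steps required
#'   (default 2).
#' @param from Earliest frame the backtrack may reach.
#' @return Frame index of reach start.
#' @export
find_reach_start <- function(hand_z, valid, slot_crossing, k = 2L, from = 1L) {
  fv <- which(valid & seq_along(hand_z) >= from & seq_along(hand_z) <= slot_crossing)
  if (length(fv) < 2) return(if (length(fv)) fv[1] else NA_integer_)
  zv <- hand_z[fv]
  v <- diff(zv)  # v[j]: velocity leaving frame fv[j]
  for (j in (length(v)):1) {
    lo <- j - k + 1L
    if (lo < 1L) break
    if (all(v[lo:j] <= 0)) return(fv[j + 1L])
  }
  fv[1]
}

#' Onset of digit-2 retraction (reach end)
#'
#' First frame after the slot crossing at which z of the digit-2 tip
#' decreases on the next valid frame, i.e. the last frame of advance.
#'
#' @param z_digit2 Per-frame z of the digit-2 tip (mm).
#' @param valid Per-frame validity.
#' @param slot_crossing Frame index of the slot crossing.
#' @param smooth `"none"` (default) or `"median3"` for a centred 3-frame
#'   median filter before extremum detection.
#' @return List `frame` (reach end) and `truncated` (`TRUE` when z never
#'   decreased before the series ended, in which case the last valid frame
#'   is returned).
#' @export
find_reach_end <- function(z_digit2, valid, slot_crossing,
                           smooth = c("none", "median3")) {
  smooth <- match.arg(smooth)
  fv <- which(valid)
  zv <- z_digit2[fv]
  if (smooth == "median3") zv <- median3(zv)
  cand <- which(fv > slot_crossing)
  if (!length(cand)) return(list(frame = NA_integer_, truncated = TRUE))
  for (j in cand) {
    if (j < length(fv) && zv[j + 1] < zv[j]) return(list(frame = fv[j], truncated = FALSE))
  }
  list(frame = fv[length(fv)], truncated = TRUE)
}

#' Grasp start and end from the digit-flexion series
#'
#' Grasp start is the first frame after the global flexion minimum (maximum
#' digit extension) within the search window at which flexion strictly
#' increases; grasp end is the first frame afterwards attaining the maximum
#' flexion of the post-grasp-start segment. Ties take the earliest frame.
#'
#' @param delta Per-frame digit-2 flexion in degrees.
#' @param valid Per-frame validity of the flexion value.
#' @param window Integer frame range to search (reach start to the end of
#'   the reach attempt).
#' @param smooth As in [find_reach_end()].
#' @return List `grasp_start`, `grasp_end`, `degenerate` (flexion monotone
#'   over the window: no grasp detectable).
#' @export
find_grasp_window <- function(delta, valid, window, smooth = c("none", "median3")) {
  smooth <- match.arg(smooth)
  fv <- intersect(which(valid), window)
  if (length(fv) < 3)
    return(list(grasp_start = NA_integer_, grasp_end = NA_integer_, degenerate = TRUE))
  dv <- delta[fv]
  if (smooth == "median3") dv <- median3(dv)
  m <- which.min(dv)  # earliest global minimum
  inc <- which(diff(dv) > 0)
  inc <- inc[inc >= m]
  if (!length(inc))
    return(list(grasp_start = NA_integer_, grasp_end = NA_integer_, degenerate = TRUE))
  gs <- inc[1] + 1L
  post <- dv[gs:length(dv)]
  ge <- gs + which.max(post) - 1L
  list(grasp_start = fv[gs], grasp_end = fv[ge], degenerate = FALSE)
}

#' Segment a trial into reach/grasp events
#'
#' Enumerates reach attempts in temporal order: each attempt begins with the
#' digits crossing the slot plane and ends when digit 2 retracts back inside
#' the slot. For each attempt the five events are detected with
#' [find_reach_start()], [find_slot_crossing()], [find_reach_end()] and
#' [find_grasp_window()]. Downstream analyses consume `reach_ordinal == 1`.
#'
#' @param traj A `trial_trajectories` object ([trial_trajectories()]) with
#'   bodyparts `hand_dorsum`, `digit1`..`digit4`, `mcp2`.
#' @param slot A [slot_geometry()].
#' @param k,smooth Passed to the event detectors.
#' @return Data frame with one row per reach: `reach_ordinal`,
#'   `reach_start`, `slot_crossing`, `reach_end`, `grasp_start`,
#'   `grasp_end`, `truncated`, `degenerate_grasp`. Zero rows when no reach
#'   is detected.
#' @export
segment_trial <- function(traj, slot = slot_geometry(), k = 2L,
                          smooth = c("none", "median3")) {
  smooth <- match.arg(smooth)
  digits <- paste0("digit", 1:4)
  dz <- sapply(digits, function(b) traj$positions[[b]][, 3])
  dvalid <- sapply(digits, function(b) traj$valid[[b]])
  z2 <- traj$positions$digit2[, 3]
  z2_valid <- traj$valid$digit2
  hz <- traj$positions$hand_dorsum[, 3]
  h_valid <- traj$valid$hand_dorsum
  delta <- digit_flexion(traj$positions$hand_dorsum, traj$positions$mcp2,
                         traj$positions$digit2)
  d_valid <- traj$valid$hand_dorsum & traj$valid$mcp2 & traj$valid$digit2 &
    !is.na(delta)
  n <- length(z2)
  out <- list(); from <- 1L; ordinal <- 0L
  repeat {
    sc <- find_slot_crossing(dz, dvalid, slot, from = from)
    if (is.na(sc)) break
    rs <- find_reach_start(hz, h_valid, sc, k = k, from = from)
    re <- find_reach_end(z2, z2_valid, sc, smooth = smooth)
    if (is.na(re$frame)) break
    # attempt ends when digit 2 drops back inside the slot plane
    after <- which(z2_valid & seq_len(n) > re$frame & z2 < slot$slot_z)
    attempt_end <- if (length(after)) after[1] else n
    gw <- find_grasp_window(delta, d_valid, seq(rs, attempt_end), smooth = smooth)
    ordinal <- ordinal + 1L
    out[[ordinal]] <- data.frame(
      reach_ordinal = ordinal, reach_start = rs, slot_crossing = sc,
      reach_end = re$frame, grasp_start = gw$grasp_start,
      grasp_end = gw$grasp_end, truncated = re$truncated,
      degenerate_grasp = gw$degenerate)
    if (attempt_end >= n) break
    from <- attempt_end + 1L
  }
  if (!length(out))
    return(data.frame(reach_ordinal = integer(0), reach_start = integer(0),
                      slot_crossing = integer(0), reach_end = integer(0),
                      grasp_start = integer(0), grasp_end = integer(0),
                      truncated = logical(0), degenerate_grasp = logical(0)))
  do.call(rbind, out)
}

#' Bundle per-bodypart 3D trajectories for one trial
#'
#' @param positions Named list of frames x 3 matrices (pellet frame, mm).
#' @param valid Named list of per-frame logical validity vectors (defaults
#'   to all-valid).
#' @param frame_rate Frames per second (default 300).
#' @param hand `"right"` or `"left"`.
#' @export
trial_trajectories <- function(positions, valid = NULL, frame_rate = 300,
                               hand = "right") {
  if (is.null(valid))
    valid <- lapply(positions, function(p) rep(TRUE, nrow(p)))
  stopifnot(identical(sort(names(positions)), sort(names(valid))))
  structure(list(positions = positions, valid = valid,
                 frame_rate = frame_rate, hand = hand),
            class = "trial_trajectories")
}
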
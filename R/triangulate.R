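# Linear (DLT) triangulation and transformation into the pellet-centred
# reference frame used throughout the kinematic analysis.

# homogeneous DLT triangulation of matched pixel points through projection
# matrices P1, P2. Returns n x 3 matrix (frame of P1).
dlt_triangulate <- function(x1, x2, P1, P2) {
  n <- nrow(x1)
  X <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    A <- rbind(x1[i, 1] * P1[3, ] - P1[1, ],
               x1[i, 2] * P1[3, ] - P1[2, ],
               x2[i, 1] * P2[3, ] - P2[1, ],
               x2[i, 2] * P2[3, ] - P2[2, ])
    v <- svd(A, nu = 0, nv = 4)$v[, 4]
    X[i, ] <- v[1:3] / v[4]
  }
  X
}

project_points <- function(X, P) {
  Xh <- cbind(X, 1) %*% t(P)
  cbind(Xh[, 1] / Xh[, 3], Xh[, 2] / Xh[, 3])
}

#' Triangulate matched two-view keypoints to 3D
#'
#' Homogeneous DLT triangulation of keypoints observed in the direct and
#' (reflected) mirror views, with per-point mean reprojection error across
#' both views. Points that land behind either camera are flagged invalid.
#' Rows with a missing observation in either view yield no 3D point
#' (`NA` row), not an error.
#'
#' @param x_direct,x_mirror n x 2 pixel coordinates; mirror coordinates are
#'   reflected internally when `calib$mirror_flip` is set. `NA` rows mark
#'   missing observations.
#' @param calib A [calibrate_mirror_views()] result (metric scale applied).
#' @return List: `points` (n x 3, mm, real-camera frame), `reproj_err_px`
#'   (mean over the two views), `valid` (present in both views and in front
#'   of both cameras).
#' @export
triangulate_points <- function(x_direct, x_mirror, calib) {
  x1 <- as.matrix(x_direct); x2 <- as.matrix(x_mirror)
  stopifnot(nrow(x1) == nrow(x2))
  if (calib$mirror_flip) x2[, 1] <- calib$camera$image_width - x2[, 1]
  n <- nrow(x1)
  ok <- complete.cases(x1) & complete.cases(x2)
  X <- matrix(NA_real_, n, 3)
  err <- rep(NA_real_, n)
  in_front <- rep(FALSE, n)
  if (any(ok)) {
    Xo <- dlt_triangulate(x1[ok, , drop = FALSE], x2[ok, , drop = FALSE],
                          calib$P_real, calib$P_virtual)
    X[ok, ] <- Xo
    p1 <- project_points(Xo, calib$P_real)
    p2 <- project_points(Xo, calib$P_virtual)
    e1 <- sqrt(rowSums((p1 - x1[ok, , drop = FALSE])^2))
    e2 <- sqrt(rowSums((p2 - x2[ok, , drop = FALSE])^2))
    err[ok] <- (e1 + e2) / 2
    t_mm <- calib$t * calib$scale
    z2 <- Xo %*% calib$R[3, ] + t_mm[3]
    in_front[ok] <- Xo[, 3] > 0 & z2 > 0
  }
  list(points = X, reproj_err_px = err, valid = ok & in_front)
}

#' Exclude 3D points with large reprojection errors
#'
#' @param errors Per-point mean reprojection errors in pixels.
#' @param threshold_px Exclusion threshold (default 10 px).
#' @return Logical mask, `FALSE` where `error > threshold_px` or the error
#'   is missing. The number of excluded points is attached as attribute
#'   `n_excluded`.
#' @export
filter_by_reprojection <- function(errors, threshold_px = 10) {
  stopifnot(threshold_px > 0)
  mask <- !is.na(errors) & errors <= threshold_px
  attr(mask, "n_excluded") <- sum(!is.na(errors) & errors > threshold_px)
  mask
}

#' Estimate the pellet origin from pre-reach frames
#'
#' Median valid 3D pellet position over the last `n_frames` valid frames
#' preceding reach start.
#'
#' @param pellet_xyz frames x 3 matrix (camera frame, mm).
#' @param valid Per-frame validity of the pellet point.
#' @param reach_start Frame index of reach start (frames at or after it are
#'   ignored).
#' @param n_frames Number of pre-reach valid frames to pool (default 10).
#' @return 3-vector, or an error if the pellet was never validly observed
#'   before the reach.
#' @export
estimate_pellet_origin <- function(pellet_xyz, valid, reach_start, n_frames = 10) {
  pre <- which(valid & seq_len(nrow(pellet_xyz)) < reach_start)
  if (!length(pre)) stop("pellet never validly observed before reach start; trial unusable")
  pre <- tail(pre, n_frames)
  apply(pellet_xyz[pre, , drop = FALSE], 2, median)
}

# camera frame -> pellet frame axis map: +x right, +y above the pellet
# (image y points down), +z beyond the pellet away from the chamber
# (toward the camera).
PELLET_AXES <- diag(c(1, -1, -1))

#' Transform camera-frame points into the pellet reference frame
#'
#' Translates so the pellet sits at the origin and re-orients the axes to
#' the analysis convention: +x to the right of the pellet, +y above it, and
#' +z on the far side of the pellet from the reaching chamber. For
#' left-handed reaches x is negated so left and right reaches are directly
#' comparable.
#'
#' @param points_camera n x 3 camera-frame points (mm).
#' @param pellet_origin 3-vector from [estimate_pellet_origin()].
#' @param hand `"right"` or `"left"`.
#' @return n x 3 matrix in the pellet frame (mm).
#' @export
to_pellet_frame <- function(points_camera, pellet_origin, hand = c("right", "left")) {
  hand <- match.arg(hand)
  P <- sweep(as.matrix(points_camera), 2, pellet_origin) %*% t(PELLET_AXES)
  if (hand == "left") P[, 1] <- -P[, 1]
  P
}

# inverse map, used by the synthetic generator to render scenes
from_pellet_frame <- function(points_pellet, pellet_origin, hand = "right") {
  P <- as.matrix(points_pellet)
  if (hand == "left") P[, 1] <- -P[, 1]
  sweep(P %*% t(solve(PELLET_AXES)), 2, -pellet_origin)
}
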
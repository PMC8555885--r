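# Arc-length-uniform trajectory resampling and the session trajectory
# variability statistic D-bar.

#' Resample a trajectory segment at 100 arc-length-uniform points
#'
#' Monotone piecewise cubic Hermite (pchip) interpolation of each
#' coordinate against cumulative chordal arc length, resampled at
#' `n_points` equally spaced stations from segment start to segment end.
#' The parameterization is purely geometric, so slow and fast traversals of
#' the same path produce matched corresponding points. Invalid frames must
#' be dropped by the caller; consecutive duplicate points (pauses) are
#' collapsed before fitting.
#'
#' @param xyz m x 3 matrix of valid segment points (mm), in time order.
#' @param n_points Number of output stations (default 100).
#' @return n_points x 3 matrix; first and last rows equal the raw segment
#'   endpoints.
#' @export
interpolate_trajectory <- function(xyz, n_points = 100) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) >= 2) {
    keep <- c(TRUE, rowSums(abs(diff(xyz))) > 0)  # collapse pauses
    xyz <- xyz[keep, , drop = FALSE]
  }
  m <- nrow(xyz)
  if (m < 2) stop("need at least 2 distinct valid points to interpolate a segment")
  s <- c(0, cumsum(sqrt(rowSums(diff(xyz)^2))))
  si <- seq(0, s[m], length.out = n_points)
  out <- sapply(1:3, function(j) signal::pchip(s, xyz[, j], si))
  out[1, ] <- xyz[1, ]; out[n_points, ] <- xyz[m, ]
  out
}

#' Session trajectory variability (mean distance from the mean trajectory)
#'
#' For interpolated trial trajectories X (trials x 100 stations x 3), the
#' session mean trajectory is the pointwise mean over trials, and the
#' variability is
#' \deqn{\bar D = \frac{1}{n}\sum_{trials}\frac{\sum_{i=1}^{100} |X_i - \bar X_i|}{100},}
#' the mean 3D Euclidean distance of each trial from the session mean, in mm.
#'
#' @param trials List of n_points x 3 matrices from
#'   [interpolate_trajectory()] (same segment type).
#' @return List: `D` (mm), `mean_trajectory` (n_points x 3), `n`.
#' @export
trajectory_variability <- function(trials) {
  n <- length(trials)
  if (n < 2) stop("trajectory variability is undefined for fewer than 2 trials")
  arr <- simplify2array(trials)          # stations x 3 x trials
  mean_traj <- apply(arr, c(1, 2), mean)
  per_trial <- vapply(seq_len(n), function(t) {
    mean(sqrt(rowSums((arr[, , t] - mean_traj)^2)))
  }, numeric(1))
  list(D = mean(per_trial), mean_trajectory = mean_traj, n = n)
}

#' Within-session variability over moving 10-trial blocks
#'
#' [trajectory_variability()] applied to each window of `block` consecutive
#' trials, using that window's own mean trajectory as the reference.
#'
#' @param trials List of interpolated trial trajectories in trial order.
#' @param block Window size (default 10).
#' @return Numeric vector of length `length(trials) - block + 1` (empty
#'   when fewer than `block` trials).
#' @export
within_session_variability <- function(trials, block = 10) {
  n <- length(trials)
  if (n < block) return(numeric(0))
  vapply(seq_len(n - block + 1), function(i) {
    trajectory_variability(trials[i:(i + block - 1)])$D
  }, numeric(1))
}
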
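# Reach-to-grasp coordination: hand-shape measures as a function of hand
# advancement, indexed by the z-coordinate of the digit-2 tip.

#' Default coordination grid
#'
#' z_digit2 stations from -20.0 mm (approaching the pellet) to +15.0 mm
#' (past it) in 0.1 mm steps: 351 points.
#' @export
coordination_grid <- function() round(seq(-20, 15, by = 0.1), 1)

#' Hand-shape profiles on the z_digit2 grid
#'
#' For the first reach of each trial, aperture, orientation and flexion are
#' interpolated (pchip) onto the z_digit2 grid over that trial's covered z
#' range only, then averaged per grid point across contributing trials.
#' Grid stations missing from shorter reaches are excluded from the
#' average; each trial's z series is reduced to its strictly increasing
#' advance before fitting.
#'
#' @param trials List of data frames, one per trial, with columns
#'   `z_digit2`, `aperture`, `orientation`, `flexion` covering the first
#'   reach (frames in time order; rows with `NA` z are dropped).
#' @param grid Grid of z stations (default [coordination_grid()]).
#' @return Object of class `coordination_profile`: data frame `z`,
#'   `aperture`, `orientation`, `flexion`, `n_trials` (contributing trial
#'   count; measures are `NA` where no trial covers the station).
#' @export
coordination_profile <- function(trials, grid = coordination_grid()) {
  measures <- c("aperture", "orientation", "flexion")
  acc <- matrix(0, length(grid), length(measures),
                dimnames = list(NULL, measures))
  cnt <- matrix(0L, length(grid), length(measures),
                dimnames = list(NULL, measures))
  for (tr in trials) {
    tr <- tr[!is.na(tr$z_digit2), , drop = FALSE]
    if (nrow(tr) < 2) next
    # strictly increasing advance of the digit tip
    keep <- c(TRUE, diff(cummax(tr$z_digit2)) > 0) & tr$z_digit2 >= cummax(tr$z_digit2)
    tr <- tr[keep, , drop = FALSE]
    if (nrow(tr) < 2) next
    covered <- grid >= min(tr$z_digit2) & grid <= max(tr$z_digit2)
    if (!any(covered)) next
    for (m in measures) {
      y <- tr[[m]]
      ok <- !is.na(y)
      if (sum(ok) < 2) next
      zi <- grid[covered]
      use <- covered & grid >= min(tr$z_digit2[ok]) & grid <= max(tr$z_digit2[ok])
      if (!any(use)) next
      val <- signal::pchip(tr$z_digit2[ok], y[ok], grid[use])
      acc[use, m] <- acc[use, m] + val
      cnt[use, m] <- cnt[use, m] + 1L
    }
  }
  out <- data.frame(z = grid)
  for (m in measures) {
    v <- acc[, m] / cnt[, m]
    v[cnt[, m] == 0] <- NA_real_
    out[[m]] <- v
    out[[paste0("n_", m)]] <- cnt[, m]
  }
  out$n_trials <- apply(cnt, 1, max)
  structure(out, class = c("coordination_profile", "data.frame"))
}

#' Sample a coordination profile at a z_digit2 station
#'
#' The between-day comparison point is z_digit2 = +3 mm past the pellet.
#'
#' @param profile A [coordination_profile()].
#' @param z Station to sample (default +3 mm; must lie on the grid).
#' @return Named list `aperture`, `orientation`, `flexion`, `n_trials`;
#'   values are `NA` (flagged via `covered = FALSE`) when no trial reaches
#'   the station.
#' @export
sample_profile <- function(profile, z = 3.0) {
  i <- which(abs(profile$z - z) < 1e-9)
  if (!length(i)) stop("z is not a grid station")
  list(aperture = profile$aperture[i], orientation = profile$orientation[i],
       flexion = profile$flexion[i], n_trials = profile$n_trials[i],
       covered = profile$n_trials[i] > 0)
}
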
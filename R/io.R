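# File interfaces: DeepLabCut-style keypoint CSVs, calibration
# correspondence tables, trial metadata, per-trial outputs.

#' Write / read one view's keypoints in the DeepLabCut CSV dialect
#'
#' Three header rows (scorer / bodyparts / coords) over x, y, likelihood
#' columns per bodypart, one row per frame.
#'
#' @param obs Data frame with columns `frame`, `bodypart`, `x`, `y`,
#'   `confidence` (one view; missing frame/bodypart combinations are
#'   written as empty cells).
#' @param path Output file.
#' @param scorer Scorer tag for the first header row.
#' @export
write_dlc_csv <- function(obs, path, scorer = "synthetic") {
  parts <- unique(obs$bodypart)
  frames <- sort(unique(obs$frame))
  ncol_ <- 3 * length(parts)
  m <- matrix(NA_real_, length(frames), ncol_)
  for (j in seq_along(parts)) {
    o <- obs[obs$bodypart == parts[j], ]
    ri <- match(o$frame, frames)
    m[ri, 3 * j - 2] <- o$x
    m[ri, 3 * j - 1] <- o$y
    m[ri, 3 * j] <- o$confidence
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("scorer", rep(scorer, ncol_)), collapse = ","), con)
  writeLines(paste(c("bodyparts", rep(parts, each = 3)), collapse = ","), con)
  writeLines(paste(c("coords", rep(c("x", "y", "likelihood"),
                                   length(parts))), collapse = ","), con)
  utils::write.table(cbind(frames, m), con, sep = ",", na = "",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dlc_csv
#' @return `read_dlc_csv` returns a long data frame `frame`, `bodypart`,
#'   `x`, `y`, `confidence`.
#' @export
read_dlc_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  parts <- strsplit(hdr[2], ",")[[1]][-1]
  dat <- utils::read.csv(path, skip = 3, header = FALSE)
  frames <- dat[[1]]
  ub <- unique(parts)
  out <- lapply(ub, function(b) {
    j <- which(parts == b)[1] + 1  # +1 for the frame column
    d <- data.frame(frame = frames, bodypart = b,
                    x = dat[[j]], y = dat[[j + 1]], confidence = dat[[j + 2]])
    d[!is.na(d$x), ]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write / read trial metadata
#'
#' @param metadata Data frame with at least `rat_id`, `day`, `trial_index`,
#'   `outcome_score`, `hand`.
#' @param path CSV file path.
#' @export
write_trial_metadata <- function(metadata, path) {
  write.csv(metadata, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_metadata
#' @export
read_trial_metadata <- function(path) read.csv(path)

#' Write calibration correspondences
#'
#' Columns: `frame`, `point_id`, `face`, `row`, `col`, `x_direct`,
#' `y_direct`, `x_mirror`, `y_mirror`.
#' @param pairs Correspondence table.
#' @param path CSV file path.
#' @export
write_correspondences <- function(pairs, path) {
  write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correspondences
#' @export
read_correspondences <- function(path) read.csv(path)

#' Write per-trial 3D trajectories
#'
#' Long CSV: `frame`, `bodypart`, `x_mm`, `y_mm`, `z_mm`, `valid`,
#' `reproj_err_px`.
#' @param traj A [trial_trajectories()].
#' @param path CSV file path.
#' @param reproj_err Optional named list of per-frame reprojection errors.
#' @export
write_trajectories_csv <- function(traj, path, reproj_err = NULL) {
  rows <- lapply(names(traj$positions), function(b) {
    p <- traj$positions[[b]]
    data.frame(frame = seq_len(nrow(p)), bodypart = b,
               x_mm = p[, 1], y_mm = p[, 2], z_mm = p[, 3],
               valid = traj$valid[[b]],
               reproj_err_px = if (is.null(reproj_err)) NA_real_
                               else reproj_err[[b]])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write ground-truth events and trajectories as JSON
#'
#' @param trial A trial element of [generate_cohort()].
#' @param path JSON file path.
#' @export
write_ground_truth_json <- function(trial, path) {
  out <- list(rat_id = trial$rat_id, day = trial$day,
              trial_index = trial$trial_index,
              outcome_score = trial$outcome_score, hand = trial$hand,
              true_events = trial$true_events)
  if (!is.null(trial$traj))
    out$positions <- lapply(trial$traj$positions, function(p) unname(as.matrix(p)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
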
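# Confidence / jump-based keypoint validity rule and the mislabeled-frame
# statistic. These criteria gate every point entering 3D reconstruction.

#' Quality thresholds for tracked keypoints
#'
#' Points with tracking confidence above `conf_high` are deemed correctly
#' labeled; below `conf_low`, mislabeled; in between, a point is mislabeled
#' if it jumped more than `jump_px` pixels from the reference frame.
#' All three boundaries are strict (confidence must exceed 0.97, fall below
#' 0.85, or the displacement must surpass 50 px).
#'
#' @param conf_high,conf_low Confidence cut points (default 0.97 / 0.85).
#' @param jump_px Displacement threshold in pixels (default 50).
#' @export
quality_thresholds <- function(conf_high = 0.97, conf_low = 0.85, jump_px = 50) {
  stopifnot(conf_low >= 0, conf_low < conf_high, conf_high <= 1, jump_px > 0)
  structure(list(conf_high = conf_high, conf_low = conf_low, jump_px = jump_px),
            class = "quality_thresholds")
}

#' Classify per-frame keypoint validity from confidence and displacement
#'
#' One bodypart in one view: confidence above `conf_high` is valid;
#' below `conf_low` mislabeled (`low_confidence`); in the intermediate band
#' the point is mislabeled (`jump`) if its Euclidean displacement from the
#' reference position exceeds `jump_px`.
#'
#' @param series Data frame sorted by frame with columns `frame`, `x`, `y`,
#'   `confidence`. Frames absent from the table are simply absent (occluded).
#' @param thresholds A [quality_thresholds()].
#' @param reference Displacement reference for the jump test:
#'   `"last_valid"` (default) uses the most recent frame already classified
#'   valid, avoiding false jumps across occlusions; `"previous"` uses the
#'   immediately preceding observed frame regardless of its label.
#' @return Data frame `frame`, `valid`, `reason` (`ok`, `low_confidence`,
#'   `jump`).
#' @export
classify_point_validity <- function(series, thresholds = quality_thresholds(),
                                    reference = c("last_valid", "previous")) {
  reference <- match.arg(reference)
  n <- nrow(series)
  if (is.null(n) || n == 0)
    return(data.frame(frame = integer(0), valid = logical(0), reason = character(0)))
  stopifnot(!is.unsorted(series$frame))
  valid <- logical(n); reason <- character(n)
  ref_xy <- NULL
  for (i in seq_len(n)) {
    conf <- series$confidence[i]
    if (conf > thresholds$conf_high) {
      valid[i] <- TRUE; reason[i] <- "ok"
    } else if (conf < thresholds$conf_low) {
      valid[i] <- FALSE; reason[i] <- "low_confidence"
    } else {
      prev <- if (reference == "previous") {
        if (i > 1) c(series$x[i - 1], series$y[i - 1]) else NULL
      } else ref_xy
      if (is.null(prev)) {  # no reference yet: no jump evidence
        valid[i] <- TRUE; reason[i] <- "ok"
      } else {
        jump <- sqrt((series$x[i] - prev[1])^2 + (series$y[i] - prev[2])^2)
        if (jump > thresholds$jump_px) {
          valid[i] <- FALSE; reason[i] <- "jump"
        } else {
          valid[i] <- TRUE; reason[i] <- "ok"
        }
      }
    }
    if (valid[i]) ref_xy <- c(series$x[i], series$y[i])
  }
  data.frame(frame = series$frame, valid = valid, reason = reason)
}

#' Percentage of mislabeled frames between reach start and grasp end
#'
#' A frame counts as mislabeled for a bodypart if the point was flagged
#' mislabeled (low confidence or jump) in either view. Frames missing from
#' both validity tables (never observed) do not count as mislabeled.
#'
#' @param validity_direct,validity_mirror Outputs of
#'   [classify_point_validity()] for the two views of one bodypart.
#' @param window Integer vector of frame indices from reach start to grasp
#'   end (inclusive).
#' @return Percentage in \[0, 100\].
#' @export
mislabeled_frame_fraction <- function(validity_direct, validity_mirror, window) {
  if (!length(window)) stop("empty reach-to-grasp window")
  bad <- function(v) v$frame[!v$valid]
  mis <- union(bad(validity_direct), bad(validity_mirror))
  100 * sum(window %in% mis) / length(window)
}
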
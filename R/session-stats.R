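# Outcome taxonomy, success rates, moving averages with carry-forward
# alignment, and the learner / non-learner classification.

# Reach outcome scores:
# 0 no pellet, 1 first success, 2 multiple success, 3 drop in box,
# 4 pellet knocked off, 5 tongue, 6 trigger error, 7 pellet remained,
# 8 non-preferred hand, 9 tongue and hand.
OUTCOME_LABELS <- c("no_pellet", "first_success", "multiple_success",
                    "drop_in_box", "pellet_knocked_off", "tongue",
                    "trigger_error", "pellet_remained", "non_preferred_hand",
                    "tongue_and_hand")
QUALIFYING_SCORES <- c(1, 2, 3, 4, 7)

#' First-reach success rate for one session
#'
#' Number of score-1 (first success) trials divided by the number of trials
#' scored 1, 2, 3, 4 or 7. Undefined (`NA`) when fewer than `min_trials`
#' qualifying trials were performed.
#'
#' @param scores Integer outcome scores (0-9) for one rat-day.
#' @param min_trials Minimum qualifying-trial count (default 10).
#' @return Fraction in \[0, 1\] or `NA`.
#' @export
first_reach_success_rate <- function(scores, min_trials = 10) {
  stopifnot(all(scores %in% 0:9))
  denom <- sum(scores %in% QUALIFYING_SCORES)
  if (denom < min_trials) return(NA_real_)
  sum(scores == 1) / denom
}

#' Moving first-success fraction over blocks of 10 reaches
#'
#' Fraction of score-1 outcomes in each moving block of `window` reaches,
#' in trial order.
#'
#' @param scores Outcome scores in trial order.
#' @param window Block size (default 10).
#' @return Numeric vector of length `length(scores) - window + 1` (empty
#'   when fewer than `window` reaches).
#' @export
moving_success_rate <- function(scores, window = 10) {
  n <- length(scores)
  if (n < window) return(numeric(0))
  x <- as.numeric(scores == 1)
  cs <- c(0, cumsum(x))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

#' Carry-forward alignment of per-rat within-session series
#'
#' Extends each rat's series by repeating its final value until all series
#' reach the group maximum length, then averages pointwise. This avoids
#' sudden changes in the group mean caused by rats performing different
#' numbers of trials (e.g. a rat with 35 trials has its trials 26-35
#' average carried forward as the 27-36, ..., 31-40 values when another rat
#' performed 40).
#'
#' @param series List of numeric vectors (one per rat), each nonempty.
#' @return List: `aligned` (rats x max-length matrix), `mean` (pointwise
#'   group mean), `carried_from` (per rat, first padded index or `NA`).
#' @export
carry_forward_align <- function(series) {
  lens <- lengths(series)
  if (!length(series) || all(lens == 0)) stop("no nonempty series to align")
  series <- series[lens > 0]; lens <- lens[lens > 0]
  m <- max(lens)
  aligned <- t(vapply(series, function(s) c(s, rep(s[length(s)], m - length(s))),
                      numeric(m)))
  list(aligned = aligned, mean = colMeans(aligned),
       carried_from = ifelse(lens < m, lens + 1L, NA_integer_))
}

#' Moving average of a kinematic measure over 10-trial blocks
#'
#' Sliding mean over `block` consecutive trials; trials with undefined
#' values are skipped (the window shrinks) and fully-undefined windows give
#' `NA`.
#'
#' @param values Per-trial values in trial order (may contain `NA`).
#' @param block Window size (default 10).
#' @return Numeric vector of window means (empty when fewer than `block`
#'   trials).
#' @export
moving_kinematic_average <- function(values, block = 10) {
  n <- length(values)
  if (n < block) return(numeric(0))
  vapply(seq_len(n - block + 1), function(i) {
    w <- values[i:(i + block - 1)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Per-outcome percentage breakdown for one rat-day
#'
#' Percentage of trials of each outcome score among all trials of the day
#' (percentages over the ten score categories sum to 100). The
#' hand-through-slot category - videos beginning with the hand already
#' through the slot, evaluated kinematically - is a flag on otherwise
#' scored trials and is reported as an additional percentage.
#'
#' @param scores Outcome scores (0-9) for one rat-day.
#' @param hand_through_slot Optional logical flag per trial.
#' @return Data frame `outcome`, `label`, `percent`, with the
#'   hand-through-slot percentage attached as attribute
#'   `hand_through_slot_percent`.
#' @export
outcome_breakdown <- function(scores, hand_through_slot = NULL) {
  n <- length(scores)
  if (n == 0) stop("no trials")
  stopifnot(all(scores %in% 0:9))
  pct <- vapply(0:9, function(s) 100 * sum(scores == s) / n, numeric(1))
  out <- data.frame(outcome = 0:9, label = OUTCOME_LABELS, percent = pct)
  attr(out, "hand_through_slot_percent") <-
    if (is.null(hand_through_slot)) NA_real_ else 100 * sum(hand_through_slot) / n
  out
}

#' Classify a rat as learner or non-learner
#'
#' Pearson chi-squared test (df = 1, no continuity correction by default)
#' comparing the proportion of first-success reaches among qualifying
#' trials (scores 1, 2, 3, 4, 7) between training days 1-2 combined and
#' days 9-10 combined. A rat is a learner iff p < alpha AND the late
#' proportion exceeds the early proportion; a significant decrease is a
#' non-learner.
#'
#' @param scores_early,scores_late Outcome scores from the two 2-day blocks.
#' @param alpha Significance level (default 0.05).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List: `chi2`, `df`, `p`, `early_prop`, `late_prop`, `direction`
#'   (`increase`/`decrease`/`flat`), `label` (`learner`/`non-learner`).
#' @export
classify_learner <- function(scores_early, scores_late, alpha = 0.05,
                             correct = FALSE) {
  qe <- scores_early[scores_early %in% QUALIFYING_SCORES]
  ql <- scores_late[scores_late %in% QUALIFYING_SCORES]
  if (!length(qe) || !length(ql))
    return(list(chi2 = NA_real_, df = 1L, p = NA_real_,
                early_prop = NA_real_, late_prop = NA_real_,
                direction = NA_character_, label = NA_character_))
  tab <- rbind(early = c(success = sum(qe == 1), other = sum(qe != 1)),
               late  = c(success = sum(ql == 1), other = sum(ql != 1)))
  pe <- tab[1, 1] / sum(tab[1, ]); pl <- tab[2, 1] / sum(tab[2, ])
  if (any(colSums(tab) == 0)) {        # no successes (or no failures) at all
    chi2 <- 0; p <- 1
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  }
  direction <- if (pl > pe) "increase" else if (pl < pe) "decrease" else "flat"
  list(chi2 = chi2, df = 1L, p = p, early_prop = pe, late_prop = pl,
       direction = direction,
       label = if (!is.na(p) && p < alpha && direction == "increase")
         "learner" else "non-learner")
}

#' Learner calls for a whole cohort metadata table
#'
#' @param metadata Data frame with columns `rat_id`, `day`, `outcome_score`.
#' @param early_days,late_days Day blocks (defaults 1-2 and 9-10).
#' @inheritParams classify_learner
#' @return Data frame, one row per rat: `rat_id`, `chi2`, `df`, `p`,
#'   `direction`, `label`.
#' @export
classify_cohort <- function(metadata, early_days = c(1, 2),
                            late_days = c(9, 10), alpha = 0.05,
                            correct = FALSE) {
  rats <- unique(metadata$rat_id)
  rows <- lapply(rats, function(r) {
    md <- metadata[metadata$rat_id == r, ]
    cl <- classify_learner(md$outcome_score[md$day %in% early_days],
                           md$outcome_score[md$day %in% late_days],
                           alpha = alpha, correct = correct)
    data.frame(rat_id = r, chi2 = cl$chi2, df = cl$df, p = cl$p,
               direction = cl$direction, label = cl$label)
  })
  do.call(rbind, rows)
}
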
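# Synthetic training cohorts: learner / non-learner schedules of success
# probability and trajectory noise across 10 daily sessions.

#' Configuration of a synthetic reaching cohort
#'
#' Defaults encode the study design this generator emulates: one session
#' per day for 10 days at 300 frames/s; learners raise their first-success
#' probability linearly from 0.10 to 0.50 while their trajectory noise
#' falls from 2.0 to 0.5 mm; non-learners hold a flat 0.25 success
#' probability and flat 1.5 mm noise. Trial counts per session are drawn
#' uniformly from `trials_per_day`.
#'
#' @param n_rats Number of rats.
#' @param group_labels Character vector (`"learner"`/`"non-learner"`) per
#'   rat; default: first `ceiling(n_rats * 2/7)` rats are learners (4 of 14).
#' @param n_days Training days (default 10).
#' @param trials_per_day Integer range (default 30-40).
#' @param success_schedule Named list of per-day first-success
#'   probabilities for each group; learner schedule must be non-decreasing.
#' @param variability_schedule Named list of per-day trajectory-noise SDs
#'   (mm); learner schedule must be non-increasing.
#' @param mislabel_rate,occlusion_rate Keypoint corruption rates for
#'   [project_to_views()].
#' @param frame_rate Hz (default 300).
#' @param endpoint_offset_scale Rigid per-trial endpoint offset SD as a
#'   multiple of the day's noise SD (default 0.5).
#' @param render_trajectories Generate 3D trajectories (default `TRUE`);
#'   disable for outcome-only simulations.
#' @param params A [reach_params()] shape model shared by the cohort.
#' @param rng_seed Integer seed; all randomness derives from it.
#' @export
cohort_config <- function(n_rats = 14,
                          group_labels = NULL,
                          n_days = 10,
                          trials_per_day = c(30, 40),
                          success_schedule = list(
                            "learner" = seq(0.10, 0.50, length.out = n_days),
                            "non-learner" = rep(0.25, n_days)),
                          variability_schedule = list(
                            "learner" = seq(2.0, 0.5, length.out = n_days),
                            "non-learner" = rep(1.5, n_days)),
                          mislabel_rate = 0, occlusion_rate = 0,
                          frame_rate = 300,
                          endpoint_offset_scale = 0.5,
                          render_trajectories = TRUE,
                          params = reach_params(),
                          rng_seed = 1) {
  if (is.null(group_labels)) {
    n_learn <- ceiling(n_rats * 2 / 7)
    group_labels <- c(rep("learner", n_learn),
                      rep("non-learner", n_rats - n_learn))
  }
  stopifnot(length(group_labels) == n_rats,
            all(group_labels %in% c("learner", "non-learner")),
            n_days >= 1, length(trials_per_day) == 2,
            trials_per_day[1] >= 1, trials_per_day[2] >= trials_per_day[1],
            mislabel_rate >= 0, mislabel_rate <= 1,
            occlusion_rate >= 0, occlusion_rate <= 1,
            frame_rate > 0)
  for (g in unique(group_labels)) {
    ss <- success_schedule[[g]]; vs <- variability_schedule[[g]]
    if (length(ss) != n_days || length(vs) != n_days)
      stop("schedule lengths must equal n_days")
    if (any(ss < 0 | ss > 1)) stop("success probabilities must be in [0, 1]")
    if (any(vs < 0)) stop("variability amplitudes must be non-negative")
  }
  if ("learner" %in% group_labels) {
    if (any(diff(success_schedule[["learner"]]) < 0))
      stop("learner success schedule must be non-decreasing")
    if (any(diff(variability_schedule[["learner"]]) > 0))
      stop("learner variability schedule must be non-increasing")
  }
  structure(list(n_rats = n_rats, group_labels = group_labels,
                 n_days = n_days, trials_per_day = trials_per_day,
                 success_schedule = success_schedule,
                 variability_schedule = variability_schedule,
                 mislabel_rate = mislabel_rate,
                 occlusion_rate = occlusion_rate,
                 frame_rate = frame_rate,
                 endpoint_offset_scale = endpoint_offset_scale,
                 render_trajectories = render_trajectories,
                 params = params, rng_seed = rng_seed),
            class = "cohort_config")
}

# scores other than 1, spread so every outcome-taxonomy path is exercised;
# scores 4 and 7 (failed first reaches) dominate as in real sessions
NON_SUCCESS_SCORES <- c(0, 2, 3, 4, 5, 6, 7, 8, 9)
NON_SUCCESS_WEIGHTS <- c(0.02, 0.06, 0.06, 0.36, 0.01, 0.02, 0.41, 0.03, 0.03)

# per-rat / per-day derived seeds, kept below 2^31. Each rat-day owns one
# sequential RNG stream: reseeding per trial makes the first draws of
# nearby streams super-uniform, which under-disperses binomial counts and
# biases downstream proportion tests.
rat_seed <- function(seed, i) (seed %% 100000L) * 1009L + i * 7919L
day_seed <- function(rs, day) (rs + day * 1000003L) %% 2147483647L

#' Generate a synthetic reaching cohort
#'
#' Draws per-day trial counts, outcome scores following each group's
#' success schedule, hand preference per rat, and (optionally) ground-truth
#' 3D trajectories whose per-frame jitter follows the group's variability
#' schedule plus a rigid per-trial endpoint offset. One sequential RNG
#' stream per rat-day, so per-rat data are reproducible independently of
#' cohort size. Deterministic given `rng_seed`.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: `config`, `metadata` (data
#'   frame `rat_id`, `group`, `day`, `trial_index`, `outcome_score`,
#'   `hand`, `hand_through_slot`, `noise_mm`), `trials` (list parallel to
#'   `metadata` rows with `true_events` and, when rendered, `traj`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  base_events <- true_events_from_params(config$params)
  v_rat <- character(0); v_grp <- character(0); v_day <- integer(0)
  v_tr <- integer(0); v_score <- integer(0); v_hand <- character(0)
  v_hts <- logical(0); v_noise <- numeric(0)
  trials <- list(); row <- 0
  for (i in seq_len(config$n_rats)) {
    rs <- rat_seed(config$rng_seed, i)
    grp <- config$group_labels[i]
    rid <- sprintf("rat%02d", i)
    set.seed(rs %% 2147483647L)
    hand <- sample(c("right", "left"), 1)
    for (d in seq_len(config$n_days)) {
      set.seed(day_seed(rs, d))
      lo <- config$trials_per_day[1]; hi <- config$trials_per_day[2]
      n_tr <- if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1) - 1L
      p_succ <- config$success_schedule[[grp]][d]
      noise <- config$variability_schedule[[grp]][d]
      succ <- runif(n_tr) < p_succ
      scores <- ifelse(succ, 1L,
                       sample(NON_SUCCESS_SCORES, n_tr, replace = TRUE,
                              prob = NON_SUCCESS_WEIGHTS))
      hts <- runif(n_tr) < 0.02
      for (tr in seq_len(n_tr)) {
        trial <- list(rat_id = rid, group = grp, day = d,
                      trial_index = tr, outcome_score = scores[tr],
                      hand = hand, true_events = base_events)
        if (config$render_trajectories) {
          off <- rnorm(3, sd = config$endpoint_offset_scale * noise)
          gen <- generate_reach_trajectory(config$params,
                                           noise_amplitude = noise,
                                           endpoint_offset = off,
                                           frame_rate = config$frame_rate)
          trial$traj <- gen$traj
          trial$endpoint_offset <- off
        }
        row <- row + 1
        trials[[row]] <- trial
      }
      v_rat <- c(v_rat, rep(rid, n_tr)); v_grp <- c(v_grp, rep(grp, n_tr))
      v_day <- c(v_day, rep(d, n_tr)); v_tr <- c(v_tr, seq_len(n_tr))
      v_score <- c(v_score, scores); v_hand <- c(v_hand, rep(hand, n_tr))
      v_hts <- c(v_hts, hts); v_noise <- c(v_noise, rep(noise, n_tr))
    }
  }
  metadata <- data.frame(rat_id = v_rat, group = v_grp, day = v_day,
                         trial_index = v_tr, outcome_score = v_score,
                         hand = v_hand, hand_through_slot = v_hts,
                         noise_mm = v_noise)
  structure(list(config = config, metadata = metadata, trials = trials),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d rats (%d learners), %d days, %d trials%s\n",
              x$config$n_rats, sum(x$config$group_labels == "learner"),
              x$config$n_days, nrow(x$metadata),
              if (x$config$render_trajectories) " (trajectories rendered)" else ""))
  invisible(x)
}
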
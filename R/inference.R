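# Group-level statistics: linear mixed models with per-rat random
# intercepts, within-session correlations, and bootstrap day-vs-day-1
# contrasts.

lmm_coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
             t = sm[, "t value"], df = sm[, "df"],
             p = sm[, "Pr(>|t|)"], row.names = NULL)
}

# a response with no variance at all carries no evidence: every slope is
# exactly zero and the mixed-model machinery degenerates, so short-circuit
constant_response_result <- function(data, terms) {
  data.frame(term = c("(Intercept)", terms),
             estimate = c(data$response[1], rep(0, length(terms))),
             t = c(Inf, rep(0, length(terms))),
             df = NA_real_,
             p = c(0, rep(1, length(terms))))
}

#' Linear mixed model for day and group effects
#'
#' Fits `response ~ day * group + (1 | rat)` with day as a numeric
#' covariate (1..n_days) and group as a two-level factor with the
#' non-learner level as reference. t statistics, Satterthwaite approximate
#' degrees of freedom and p values are reported per fixed-effect term.
#' With a single group the group terms are dropped with a warning.
#'
#' @param data Data frame with columns `rat`, `day`, `group`, `response`
#'   (rows with `NA` response are omitted).
#' @return List: `coefficients` (term, estimate, t, df, p),
#'   `ranef_variance` (per-rat random-intercept variance), `fit`.
#' @export
fit_group_day_model <- function(data) {
  data <- data[!is.na(data$response), ]
  stopifnot(length(unique(data$rat)) >= 2, length(unique(data$day)) >= 2)
  data$day <- as.numeric(data$day)
  lv <- unique(as.character(data$group))
  if (sd(data$response) < 1e-10) {
    terms <- if (length(lv) < 2) "day" else
      c("day", paste0("group", setdiff(lv, "non-learner")[1]),
        paste0("day:group", setdiff(lv, "non-learner")[1]))
    return(list(coefficients = constant_response_result(data, terms),
                ranef_variance = 0, fit = NULL))
  }
  if (length(lv) < 2) {
    warning("single group level: group terms omitted")
    fit <- lmerTest::lmer(response ~ day + (1 | rat), data = data, REML = TRUE)
  } else {
    ref <- if ("non-learner" %in% lv) "non-learner" else lv[1]
    data$group <- stats::relevel(factor(data$group), ref = ref)
    fit <- lmerTest::lmer(response ~ day * group + (1 | rat), data = data,
                          REML = TRUE)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(coefficients = lmm_coef_table(fit),
       ranef_variance = vc$vcov[vc$grp == "rat"], fit = fit)
}

#' Linear mixed model for day and outcome (hit/miss) effects
#'
#' As [fit_group_day_model()] with reach outcome (successful vs failed
#' first reach) replacing group; intended to be fitted separately per
#' learner group.
#'
#' @param data Data frame with columns `rat`, `day`, `outcome` (two
#'   levels, e.g. `"hit"`/`"miss"`), `response`.
#' @return As [fit_group_day_model()].
#' @export
fit_outcome_day_model <- function(data) {
  data <- data[!is.na(data$response), ]
  if (length(unique(as.character(data$outcome))) < 2)
    stop("both outcome levels must be present")
  data$day <- as.numeric(data$day)
  data$outcome <- factor(data$outcome)
  if (sd(data$response) < 1e-10) {
    lv2 <- levels(data$outcome)[2]
    terms <- c("day", paste0("outcome", lv2), paste0("day:outcome", lv2))
    return(list(coefficients = constant_response_result(data, terms),
                ranef_variance = 0, fit = NULL))
  }
  fit <- lmerTest::lmer(response ~ day * outcome + (1 | rat), data = data,
                        REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(coefficients = lmm_coef_table(fit),
       ranef_variance = vc$vcov[vc$grp == "rat"], fit = fit)
}

#' Correlation between within-session variability and success rate
#'
#' Pearson correlation with two-sided p value between aligned moving-window
#' series of trajectory variability and first-success rate.
#'
#' @param variability,success Aligned numeric series (length >= 3).
#' @return List: `r`, `p`, `n`. `NA` values are dropped pairwise; constant
#'   series give an error.
#' @export
success_variability_correlation <- function(variability, success) {
  ok <- !is.na(variability) & !is.na(success)
  x <- variability[ok]; y <- success[ok]
  if (length(x) < 3) stop("need at least 3 aligned pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for a constant series")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bootstrap estimate of the mean difference between each day and day 1
#'
#' For each day beyond the reference, both days' values are resampled with
#' replacement `n_resamples` times; the difference in means and its
#' percentile 95% confidence interval are reported. Deterministic given
#' `seed`.
#'
#' @param values Numeric vector of per-trial (or per-session) values.
#' @param day Matching day labels.
#' @param reference Reference day (default 1).
#' @param n_resamples Number of bootstrap resamples (default 5000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Data frame: `day`, `diff` (mean difference vs reference),
#'   `ci_low`, `ci_high`, `n`.
#' @export
bootstrap_day_difference <- function(values, day, reference = 1,
                                     n_resamples = 5000, conf = 0.95,
                                     seed = 1) {
  set.seed(seed)
  ref <- values[day == reference & !is.na(values)]
  if (length(ref) < 2) stop("need at least 2 values on the reference day")
  days <- setdiff(sort(unique(day)), reference)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  rows <- lapply(days, function(d) {
    v <- values[day == d & !is.na(values)]
    if (length(v) < 2) {
      warning(sprintf("day %s skipped: fewer than 2 values", d))
      return(NULL)
    }
    boots <- vapply(seq_len(n_resamples), function(i) {
      mean(sample(v, replace = TRUE)) - mean(sample(ref, replace = TRUE))
    }, numeric(1))
    ci <- unname(quantile(boots, probs, type = 7))
    data.frame(day = d, diff = mean(v) - mean(ref),
               ci_low = ci[1], ci_high = ci[2], n = length(v))
  })
  do.call(rbind, rows)
}
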
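# Linkage of model appraisals to trial-wise self-reports: mixed-effects
# slope of a rating on a model-derived value, with a two-stage fallback.

#' Regress trial-wise ratings on model-derived values
#'
#' Tests whether a model internal (e.g. perceived care) tracks a
#' self-report (e.g. the care rating) across trials. Both variables are
#' z-scored over the full sample, then a linear mixed model with random
#' intercept and slope by participant is fitted
#' (`rating ~ value + (1 + value | participant)`). If the mixed fit fails
#' or does not converge, a documented two-stage fallback is used:
#' per-participant OLS slopes followed by a one-sample t-test of their
#' mean.
#'
#' @param values Numeric vector of model-derived trial values.
#' @param ratings Numeric vector of self-reports, same length.
#' @param participant Vector of participant identifiers, same length.
#' @param predictor,outcome Labels recorded in the result.
#' @return A `linkage_result`: list with `beta` (standardized slope), `se`,
#'   `statistic` (t), `p_value`, `n_participants`, `n_trials`, and `method`
#'   (`"mixed"` or `"two_stage"`).
#' @examples
#' \donttest{
#' co <- simulate_cohort(8, seed = 2)
#' with(co$trials,
#'   linkage_regression(omega, rating_care, participant,
#'                      "perceived_care", "care_rating"))
#' }
#' @export
linkage_regression <- function(values, ratings, participant,
                               predictor = "model_value",
                               outcome = "rating") {
  stopifnot(length(values) == length(ratings),
            length(values) == length(participant))
  keep <- is.finite(values) & is.finite(ratings)
  values <- values[keep]; ratings <- ratings[keep]
  participant <- participant[keep]
  ids <- unique(participant)
  if (length(ids) < 2) stop_input("need at least 2 participants")
  if (min(table(participant)) < 4) {
    stop_input("need at least 4 trials per participant")
  }
  within_sd <- tapply(values, participant, stats::sd)
  if (all(within_sd == 0)) {
    stop_input("predictor has zero variance within every participant")
  }

  z <- function(x) (x - mean(x)) / stats::sd(x)
  dat <- data.frame(v = z(values), r = z(ratings),
                    id = factor(participant))

  mixed <- tryCatch({
    fit <- suppressMessages(
      lme4::lmer(r ~ v + (1 + v | id), data = dat,
                 control = lme4::lmerControl(calc.derivs = FALSE)))
    if (length(fit@optinfo$conv$lme4$messages) > 0) NULL else fit
  }, error = function(e) NULL, warning = function(w) NULL)

  if (!is.null(mixed)) {
    co <- summary(mixed)$coefficients
    beta <- co["v", "Estimate"]; se <- co["v", "Std. Error"]
    stat <- co["v", "t value"]
    df <- length(ids) - 1
    p <- 2 * stats::pt(abs(stat), df = df, lower.tail = FALSE)
    method <- "mixed"
  } else {
    slopes <- vapply(ids, function(i) {
      d <- dat[dat$id == i, ]
      if (stats::sd(d$v) == 0) return(NA_real_)
      stats::coef(stats::lm(r ~ v, data = d))[["v"]]
    }, numeric(1))
    slopes <- slopes[is.finite(slopes)]
    tt <- stats::t.test(slopes)
    beta <- mean(slopes); se <- stats::sd(slopes) / sqrt(length(slopes))
    stat <- unname(tt$statistic); p <- tt$p.value
    method <- "two_stage"
  }

  structure(list(predictor = predictor, outcome = outcome, beta = beta,
                 se = se, statistic = stat, p_value = p,
                 n_participants = length(ids), n_trials = nrow(dat),
                 method = method),
            class = "linkage_result")
}

#' @exportS3Method base::print
print.linkage_result <- function(x, ...) {
  cat(sprintf(
    "<linkage %s -> %s> beta = %.3f (SE %.3f), t = %.2f, p = %.3g [%s, %d participants]\n",
    x$predictor, x$outcome, x$beta, x$se, x$statistic, x$p_value,
    x$method, x$n_participants))
  invisible(x)
}

#' Run the standard appraisal-rating linkage battery
#'
#' Applies [linkage_regression()] to the canonical appraisal-rating pairs
#' of a cohort table: second-order belief vs the belief rating, perceived
#' care vs the care/guilt/gratitude ratings, and the normalized belief vs
#' the obligation rating.
#'
#' @param trials Long trial table with appraisal and rating columns (as
#'   produced by [simulate_cohort()] or [read_trials()] plus [appraise()]).
#' @return Data frame with one row per pair (tidy `linkage_result`s).
#' @export
linkage_battery <- function(trials) {
  pairs <- list(
    c("e_second", "rating_belief"),
    c("omega", "rating_care"),
    c("omega", "rating_guilt"),
    c("omega", "rating_gratitude"),
    c("e_second", "rating_obligation")
  )
  rows <- lapply(pairs, function(pr) {
    res <- linkage_regression(trials[[pr[1]]], trials[[pr[2]]],
                              trials$participant, pr[1], pr[2])
    as.data.frame(unclass(res), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
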
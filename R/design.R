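# Task designs emulating the interpersonal helping game: a benefactor spends
# part of a 20-yuan endowment to reduce the participant's pain, crossed with
# whether the benefactor knew repayment (from the participant's 25-yuan
# endowment) was possible.

DEFAULT_COST_LEVELS <- seq(0, 16, by = 2)
DEFAULT_MU_LEVELS <- c(0.5, 1.0, 1.5)
MAX_PAIN_REDUCTION <- 16 # seconds; some pain always remains

#' Generate a task design
#'
#' Builds one participant's trial table for the three supported layouts:
#' \describe{
#'   \item{`"2a"`}{48 trials: 24 per intention condition, each condition
#'     split 12 forced-accept / 12 free-choice; fixed efficiency `mu = 1`.}
#'   \item{`"2b"`}{56 trials: 28 per condition with efficiency varying over
#'     `mu_levels` (combinations violating the 16-second pain-reduction cap
#'     are excluded).}
#'   \item{`"fmri"`}{48 trials: 24 per condition, all forced-accept (the
#'     scanner task offers no rejection option).}
#' }
#' Benefactor costs tile `cost_levels`; trial order is shuffled by `seed`.
#'
#' @param study `"2a"`, `"2b"` or `"fmri"`.
#' @param seed Integer seed controlling the trial-order shuffle.
#' @param cost_levels Benefactor cost levels (yuan, within \[0, 20\]).
#' @param mu_levels Efficiency levels used by the `"2b"` layout.
#' @return Data frame of class `trial_design` with columns `trial_id`,
#'   `condition`, `choice_type`, `d_a`, `mu`, `gamma_a`, `gamma_b`,
#'   `max_benefit`.
#' @examples
#' d <- make_design("2a", seed = 1)
#' table(d$condition, d$choice_type)
#' @export
make_design <- function(study = c("2a", "2b", "fmri"), seed = 1,
                        cost_levels = DEFAULT_COST_LEVELS,
                        mu_levels = DEFAULT_MU_LEVELS) {
  study <- match.arg(study)
  if (length(cost_levels) < 1 || any(cost_levels < 0 | cost_levels > 20)) {
    stop_input("`cost_levels` must lie within [0, 20]")
  }
  per_cond <- switch(study, "2a" = 24L, "2b" = 28L, "fmri" = 24L)

  if (study == "2b") {
    cells <- expand.grid(d_a = cost_levels, mu = mu_levels)
    cells <- cells[cells$d_a * cells$mu <= MAX_PAIN_REDUCTION, , drop = FALSE]
  } else {
    cells <- data.frame(d_a = cost_levels, mu = 1.0)
  }
  idx <- rep_len(seq_len(nrow(cells)), per_cond)

  one_condition <- function(cond, choice_types) {
    data.frame(
      condition = cond,
      choice_type = choice_types,
      d_a = cells$d_a[idx],
      mu = cells$mu[idx],
      stringsAsFactors = FALSE
    )
  }
  half <- per_cond / 2
  choice_types <- if (study == "fmri") {
    rep("force_accept", per_cond)
  } else {
    rep(c("force_accept", "free_choice"), each = half)
  }
  des <- rbind(
    one_condition("repayment_impossible", choice_types),
    one_condition("repayment_possible", choice_types)
  )
  des <- with_seed(seed, des[sample.int(nrow(des)), , drop = FALSE])
  des$trial_id <- seq_len(nrow(des))
  des$gamma_a <- 20
  des$gamma_b <- 25
  des$max_benefit <- min(max(des$d_a * des$mu), MAX_PAIN_REDUCTION)
  rownames(des) <- NULL
  des <- des[, c("trial_id", "condition", "choice_type", "d_a", "mu",
                 "gamma_a", "gamma_b", "max_benefit")]
  class(des) <- c("trial_design", "data.frame")
  des
}
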
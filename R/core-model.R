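# Core utility mathematics: appraisals, component utilities, total utility,
# the closed-form / grid reciprocity optimum, and the acceptance choice rule.
# All functions are vectorized over trials and pure (no RNG).

#' Second-order belief about expected repayment
#'
#' The beneficiary's belief about how much the benefactor expects to be
#' repaid. When the benefactor was told repayment is impossible, no repayment
#' can be expected and the belief is zero; when the benefactor knew repayment
#' was possible, the belief equals the benefactor's cost.
#'
#' @param condition Character vector, `"repayment_impossible"` or
#'   `"repayment_possible"`.
#' @param d_a Benefactor cost in yuan (0 to `gamma_a`); vector recycled
#'   against `condition`.
#' @return Numeric vector of beliefs in yuan.
#' @examples
#' second_order_belief("repayment_possible", 10)   # 10
#' second_order_belief("repayment_impossible", 10) # 0
#' @export
second_order_belief <- function(condition, d_a) {
  condition <- match_condition(condition)
  if (any(!is.finite(d_a)) || any(d_a < 0)) {
    stop_input("`d_a` must be finite and non-negative")
  }
  ifelse(condition == "repayment_possible", d_a, 0)
}

match_condition <- function(condition) {
  ok <- condition %in% c("repayment_impossible", "repayment_possible")
  if (any(!ok)) {
    stop_input("`condition` must be 'repayment_impossible' or 'repayment_possible'")
  }
  condition
}

#' Perceived care appraisal
#'
#' Perceived altruistic intent: the benefactor's cost as a fraction of their
#' endowment, discounted by the strategic expectation of repayment. The
#' discount weight `kappa` captures how much a perceived strategic motive
#' undercuts perceived care:
#' `omega = (d_a - kappa * e_second) / gamma_a`.
#'
#' @param d_a Benefactor cost (yuan).
#' @param e_second Second-order belief (yuan), see [second_order_belief()].
#' @param kappa Intention discount in \[0, 1\].
#' @param gamma_a Benefactor endowment (yuan, > 0). Default 20.
#' @return Perceived care as a dimensionless fraction (in \[0, 1\] for
#'   in-range inputs).
#' @examples
#' perceived_care(10, 0, 0.32)  # 0.5: no expected repayment, no discount
#' perceived_care(10, 10, 1)    # 0:   fully strategic help
#' @export
perceived_care <- function(d_a, e_second, kappa, gamma_a = 20) {
  if (any(!is.finite(gamma_a)) || any(gamma_a <= 0)) {
    stop_input("`gamma_a` must be positive")
  }
  if (any(kappa < 0 | kappa > 1)) stop_input("`kappa` must be in [0, 1]")
  if (any(d_a < 0)) stop_input("`d_a` must be non-negative")
  (d_a - kappa * e_second) / gamma_a
}

#' Trial appraisals from a design
#'
#' Convenience wrapper computing both appraisals (second-order belief and
#' perceived care) for every row of a trial design.
#'
#' @param design Data frame with columns `condition`, `d_a`, `gamma_a`.
#' @param kappa Intention discount in \[0, 1\].
#' @return Data frame with columns `e_second` (yuan) and `omega` (fraction).
#' @export
appraise <- function(design, kappa) {
  e2 <- second_order_belief(design$condition, design$d_a)
  om <- perceived_care(design$d_a, e2, kappa, design$gamma_a)
  data.frame(e_second = e2, omega = om)
}

#' Utility of a reciprocity decision, with components
#'
#' Total utility of returning `d_b` yuan after receiving help, decomposed
#' into self-interest (fraction of endowment kept, weighted by greed
#' `theta`) and two negative quadratic penalties: communal concern (distance
#' of `d_b` from the care-proportional target `omega * gamma_b`) and
#' obligation (distance from the expected repayment `e_second`), traded off
#' by `phi`:
#'
#' `U = theta * (gamma_b - d_b)/gamma_b - (1 - theta) *
#'   (phi * ((omega*gamma_b - d_b)/gamma_b)^2 +
#'    (1 - phi) * ((e_second - d_b)/gamma_b)^2)`
#'
#' @param d_b Reciprocity amount(s), yuan in \[0, `gamma_b`\].
#' @param theta,phi Greed and tradeoff weights, both in \[0, 1\].
#' @param e_second,omega Trial appraisals (see [appraise()]).
#' @param gamma_b Participant endowment (yuan). Default 25.
#' @return Data frame with columns `self_interest`, `u_communal`,
#'   `u_obligation` and `utility`.
#' @examples
#' reciprocity_utility(12.5, theta = 0, phi = 1, e_second = 0, omega = 0.5)
#' @export
reciprocity_utility <- function(d_b, theta, phi, e_second, omega,
                                gamma_b = 25) {
  if (any(d_b < 0 | d_b > gamma_b)) {
    stop_input("`d_b` must lie in [0, gamma_b]")
  }
  if (any(theta < 0 | theta > 1)) stop_input("`theta` must be in [0, 1]")
  if (any(phi < 0 | phi > 1)) stop_input("`phi` must be in [0, 1]")
  pi_b <- (gamma_b - d_b) / gamma_b
  u_com <- -((omega * gamma_b - d_b) / gamma_b)^2
  u_obl <- -((e_second - d_b) / gamma_b)^2
  u <- theta * pi_b + (1 - theta) * (phi * u_com + (1 - phi) * u_obl)
  data.frame(self_interest = pi_b, u_communal = u_com,
             u_obligation = u_obl, utility = u)
}

#' Utility-maximizing reciprocity amount
#'
#' The amount on the 0.1-yuan response grid maximizing the reciprocity
#' utility. For `theta < 1` the unconstrained maximizer has the closed form
#' `phi*omega*gamma_b + (1-phi)*e_second - theta*gamma_b/(2*(1-theta))`,
#' which is clipped to \[0, `gamma_b`\] and snapped to the grid; at
#' `theta = 1` utility is pure self-interest and the optimum is 0.
#'
#' @inheritParams reciprocity_utility
#' @param snap Snap the result to the 0.1-yuan grid (default `TRUE`).
#'   `FALSE` returns the continuous clipped optimum, used internally for
#'   smooth fitting objectives.
#' @return Numeric vector of optimal amounts (yuan).
#' @examples
#' optimal_reciprocity(theta = 0, phi = 1, e_second = 0, omega = 0.5) # 12.5
#' optimal_reciprocity(theta = 0, phi = 0, e_second = 10, omega = 0.5) # 10
#' @export
optimal_reciprocity <- function(theta, phi, e_second, omega, gamma_b = 25,
                                snap = TRUE) {
  if (any(theta < 0 | theta > 1)) stop_input("`theta` must be in [0, 1]")
  if (any(phi < 0 | phi > 1)) stop_input("`phi` must be in [0, 1]")
  target <- phi * omega * gamma_b + (1 - phi) * e_second
  # greed pulls the optimum below the appraisal target; diverges as theta -> 1
  pull <- ifelse(theta >= 1, Inf, theta * gamma_b / (2 * (1 - theta)))
  d_star <- clip(target - pull, 0, gamma_b)
  d_star[theta >= 1] <- 0
  if (snap) snap_to_grid(d_star) else d_star
}

#' Brute-force grid argmax of reciprocity utility
#'
#' Independent reference optimizer: evaluates the utility on the full
#' response grid and returns the argmax (lowest amount on ties). Used to
#' validate the closed form; O(grid) per trial.
#'
#' @inheritParams reciprocity_utility
#' @return Optimal amount (yuan), scalar.
#' @export
grid_optimal_reciprocity <- function(theta, phi, e_second, omega,
                                     gamma_b = 25) {
  grid <- seq(0, gamma_b, by = GRID_STEP)
  u <- reciprocity_utility(grid, theta, phi, e_second, omega, gamma_b)$utility
  grid[which.max(u)]
}

#' Utilities of accepting vs rejecting help
#'
#' In the help-acceptance model self-interest is the fraction of the maximum
#' possible pain relief obtained (`d_a * mu / max_benefit`), communal concern
#' is linear in perceived care, and obligation is linear in the normalized
#' second-order belief. The signed tradeoff `phi` separates gratitude
#' (`phi > 0`, care motivates accepting) from guilt (`phi < 0`, care
#' motivates rejecting), with `1 - |phi|` weighting obligation, which always
#' opposes acceptance. Rejecting leaves feelings unchanged, so
#' `U(reject) = 0`.
#'
#' @param theta Greed weight in \[0, 1\].
#' @param phi Signed tradeoff in \[-1, 1\].
#' @param d_a Benefactor cost (yuan).
#' @param mu Help efficiency (seconds of pain reduction per yuan).
#' @param max_benefit Design-wide maximum of `d_a * mu` (seconds, > 0).
#' @param e_second,omega Trial appraisals.
#' @param gamma_b Participant endowment (yuan). Default 25.
#' @return Data frame with columns `u_accept` and `u_reject`.
#' @examples
#' acceptance_utilities(theta = 0, phi = -1, d_a = 10, mu = 1,
#'                      max_benefit = 16, e_second = 0, omega = 0.5)
#' @export
acceptance_utilities <- function(theta, phi, d_a, mu, max_benefit,
                                 e_second, omega, gamma_b = 25) {
  if (any(phi < -1 | phi > 1)) stop_input("`phi` must be in [-1, 1]")
  if (any(max_benefit <= 0 & d_a > 0)) {
    stop_input("`max_benefit` must be positive when `d_a` > 0")
  }
  pi_b <- ifelse(d_a > 0, d_a * mu / max_benefit, 0)
  u_acc <- theta * pi_b +
    (1 - theta) * (phi * omega - (1 - abs(phi)) * e_second / gamma_b)
  data.frame(u_accept = u_acc, u_reject = 0)
}

#' Probability of accepting help
#'
#' Logistic choice rule over the accept-reject utility difference with
#' temperature `tau`: `P(accept) = 1 / (1 + exp(-tau * (u_accept -
#' u_reject)))`. Strictly increasing in `u_accept`.
#'
#' @param u_accept,u_reject Utilities of the two options.
#' @param tau Choice temperature (> 0); large values approach deterministic
#'   utility maximization.
#' @return Acceptance probabilities in (0, 1).
#' @examples
#' accept_probability(1, 0, tau = 1)  # ~0.731
#' @export
accept_probability <- function(u_accept, u_reject, tau) {
  if (any(tau <= 0)) stop_input("`tau` must be positive")
  1 / (1 + exp(-tau * (u_accept - u_reject)))
}
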
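# Model registry: the main utility models (1.1 reciprocity, 2.1 acceptance)
# plus the comparison family, behind one interface so fitting and comparison
# code is model-agnostic.
#
# The exact functional forms of the comparison models are described only
# briefly in the source study; the implementations here follow those
# one-line descriptions plus standard formulations (linear tit-for-tat
# target; symmetric Fehr-Schmidt-style quadratic inequity penalty without
# advantageous/disadvantageous asymmetry; separate-weight models with
# unnormalized weights). Each choice is isolated in this file.

#' Build a model specification
#'
#' Returns a `model_spec` describing one member of the model family:
#' parameter names and bounds, the decision type, and a prediction function.
#' Reciprocity specs predict continuous reciprocity amounts; acceptance
#' specs predict acceptance probabilities.
#'
#' Registry (reciprocity): `"1.1"` full quadratic tradeoff model; `"1.2"`
#' linear (absolute-difference) penalties; `"1.3"` communal-only
#' (`phi = 1`); `"1.4"` obligation-only (`phi = 0`); `"1.5"`/`"1.6"`
#' separate weights on self-interest/communal/obligation with and without
#' the intention discount; `"1.7"` tit-for-tat (reciprocity proportional to
#' cost); `"1.8"` inequity aversion (quadratic penalty on the payoff gap).
#' Acceptance: `"2.1"` full signed-tradeoff model; `"2.2"` communal-only;
#' `"2.3"` obligation-only; `"2.4"`/`"2.5"` separate weights with and
#' without the intention discount.
#'
#' @param name Model name, e.g. `"1.1"` or `"2.3"`.
#' @return A `model_spec` list with elements `name`, `decision`,
#'   `par_names`, `lower`, `upper`, and `predict(par, trials)`.
#' @examples
#' m <- build_model("1.1")
#' m$par_names
#' @export
build_model <- function(name) {
  name <- as.character(name)
  builder <- model_registry()[[name]]
  if (is.null(builder)) {
    stop_input(sprintf("unknown model '%s'; see names(model_registry())", name))
  }
  builder()
}

#' Model registry
#'
#' @return Named list of model builders; `names()` gives the available
#'   model identifiers.
#' @export
model_registry <- function() {
  list(
    "1.1" = function() recip_spec("1.1", c("theta", "phi", "kappa"),
      lower = c(0, 0, 0), upper = c(1, 1, 1),
      function(par, tr) {
        app <- appraise(tr, par[["kappa"]])
        optimal_reciprocity(par[["theta"]], par[["phi"]], app$e_second,
                            app$omega, tr$gamma_b, snap = FALSE)
      }),
    "1.2" = function() recip_spec("1.2", c("theta", "phi", "kappa"),
      lower = c(0, 0, 0), upper = c(1, 1, 1),
      function(par, tr) {
        app <- appraise(tr, par[["kappa"]])
        predict_linear_penalty(par[["theta"]], par[["phi"]], app$e_second,
                               app$omega, tr$gamma_b)
      }),
    "1.3" = function() recip_spec("1.3", c("theta", "kappa"),
      lower = c(0, 0), upper = c(1, 1),
      function(par, tr) {
        app <- appraise(tr, par[["kappa"]])
        optimal_reciprocity(par[["theta"]], 1, app$e_second, app$omega,
                            tr$gamma_b, snap = FALSE)
      }),
    "1.4" = function() recip_spec("1.4", "theta", lower = 0, upper = 1,
      function(par, tr) {
        app <- appraise(tr, 0)
        optimal_reciprocity(par[["theta"]], 0, app$e_second, app$omega,
                            tr$gamma_b, snap = FALSE)
      }),
    "1.5" = function() recip_spec("1.5",
      c("theta1", "theta2", "theta3", "kappa"),
      lower = rep(0, 4), upper = rep(1, 4),
      function(par, tr) {
        app <- appraise(tr, par[["kappa"]])
        predict_separate_weights(par[["theta1"]], par[["theta2"]],
                                 par[["theta3"]], app$e_second, app$omega,
                                 tr$gamma_b)
      }),
    "1.6" = function() recip_spec("1.6", c("theta1", "theta2", "theta3"),
      lower = rep(0, 3), upper = rep(1, 3),
      function(par, tr) {
        app <- appraise(tr, 0)
        predict_separate_weights(par[["theta1"]], par[["theta2"]],
                                 par[["theta3"]], app$e_second, app$omega,
                                 tr$gamma_b)
      }),
    "1.7" = function() recip_spec("1.7", "slope", lower = 0, upper = 2,
      function(par, tr) clip(par[["slope"]] * tr$d_a, 0, tr$gamma_b)),
    "1.8" = function() recip_spec("1.8", "theta", lower = 0, upper = 1,
      function(par, tr) {
        theta <- par[["theta"]]
        # equal-payoff point of gamma_B - D vs gamma_A - D_A + D, shifted
        # down by greed; quadratic gap penalty gives the closed form
        pull <- if (theta >= 1) Inf else theta * tr$gamma_b / (8 * (1 - theta))
        d <- clip((tr$gamma_b + tr$d_a - tr$gamma_a) / 2 - pull, 0, tr$gamma_b)
        d[!is.finite(d)] <- 0
        d
      }),
    "2.1" = function() accept_spec("2.1", c("theta", "phi", "kappa", "tau"),
      lower = c(0, -1, 0, 0.01), upper = c(1, 1, 1, 20),
      function(par, tr) {
        app <- appraise(tr, par[["kappa"]])
        u <- acceptance_utilities(par[["theta"]], par[["phi"]], tr$d_a,
                                  tr$mu, tr$max_benefit, app$e_second,
                                  app$omega, tr$gamma_b)
        accept_probability(u$u_accept, u$u_reject, par[["tau"]])
      }),
    "2.2" = function() accept_spec("2.2", c("theta", "phi", "kappa", "tau"),
      lower = c(0, -1, 0, 0.01), upper = c(1, 1, 1, 20),
      function(par, tr) {
        app <- appraise(tr, par[["kappa"]])
        pi_b <- relief_fraction(tr)
        u <- par[["theta"]] * pi_b + (1 - par[["theta"]]) * par[["phi"]] * app$omega
        accept_probability(u, 0, par[["tau"]])
      }),
    "2.3" = function() accept_spec("2.3", c("theta", "tau"),
      lower = c(0, 0.01), upper = c(1, 20),
      function(par, tr) {
        e2 <- second_order_belief(tr$condition, tr$d_a)
        pi_b <- relief_fraction(tr)
        u <- par[["theta"]] * pi_b - (1 - par[["theta"]]) * e2 / tr$gamma_b
        accept_probability(u, 0, par[["tau"]])
      }),
    "2.4" = function() accept_spec("2.4",
      c("theta1", "theta2", "theta3", "kappa", "tau"),
      lower = c(0, -1, 0, 0, 0.01), upper = c(1, 1, 1, 1, 20),
      function(par, tr) {
        app <- appraise(tr, par[["kappa"]])
        u <- par[["theta1"]] * relief_fraction(tr) +
          par[["theta2"]] * app$omega - par[["theta3"]] * app$e_second / tr$gamma_b
        accept_probability(u, 0, par[["tau"]])
      }),
    "2.5" = function() accept_spec("2.5",
      c("theta1", "theta2", "theta3", "tau"),
      lower = c(0, -1, 0, 0.01), upper = c(1, 1, 1, 20),
      function(par, tr) {
        app <- appraise(tr, 0)
        u <- par[["theta1"]] * relief_fraction(tr) +
          par[["theta2"]] * app$omega - par[["theta3"]] * app$e_second / tr$gamma_b
        accept_probability(u, 0, par[["tau"]])
      })
  )
}

relief_fraction <- function(tr) {
  ifelse(tr$d_a > 0, tr$d_a * tr$mu / tr$max_benefit, 0)
}

recip_spec <- function(name, par_names, lower, upper, predict) {
  structure(list(name = name, decision = "reciprocity",
                 par_names = par_names,
                 lower = stats::setNames(lower, par_names),
                 upper = stats::setNames(upper, par_names),
                 predict = predict),
            class = "model_spec")
}

accept_spec <- function(name, par_names, lower, upper, predict) {
  structure(list(name = name, decision = "acceptance",
                 par_names = par_names,
                 lower = stats::setNames(lower, par_names),
                 upper = stats::setNames(upper, par_names),
                 predict = predict),
            class = "model_spec")
}

#' @exportS3Method base::print
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s (%s)> parameters: %s\n",
              x$name, x$decision, paste(x$par_names, collapse = ", ")))
  invisible(x)
}

# Linear-penalty model: utility is piecewise linear in d_b, so the optimum
# sits at a kink (the two appraisal targets) or a boundary.
predict_linear_penalty <- function(theta, phi, e_second, omega, gamma_b) {
  n <- length(e_second)
  gb <- rep_len(gamma_b, n)
  cand <- cbind(0, clip(omega * gb, 0, gb), clip(e_second, 0, gb), gb)
  u_of <- function(d, i) {
    theta * (gb[i] - d) / gb[i] -
      (1 - theta) * (phi * abs(omega[i] * gb[i] - d) +
                     (1 - phi) * abs(e_second[i] - d)) / gb[i]
  }
  vapply(seq_len(n), function(i) {
    u <- u_of(cand[i, ], i)
    cand[i, which.max(u)]
  }, numeric(1))
}

# Separate-weight quadratic model: self-interest weight theta1 competes
# with unnormalized communal (theta2) and obligation (theta3) penalties.
predict_separate_weights <- function(theta1, theta2, theta3,
                                     e_second, omega, gamma_b) {
  w <- theta2 + theta3
  if (w <= 0) return(rep_len(0, length(e_second)))
  target <- (theta2 * omega * gamma_b + theta3 * e_second) / w
  clip(target - theta1 * gamma_b / (2 * w), 0, gamma_b)
}
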
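# Synthetic agents: generative model for decisions and self-reports on a
# task design, plus population sampling for recovery and power studies.

#' Simulate one agent on a task design
#'
#' Plays a parameterized agent through every trial of a design. Per trial the
#' agent forms appraisals ([appraise()]), picks the reciprocity amount as the
#' utility optimum perturbed by Gaussian decision noise `sigma_d` (censored
#' at the endowment bounds, then snapped to the 0.1-yuan grid), and on
#' free-choice trials samples accept/reject from the logistic choice rule;
#' forced trials are always accepted. Self-reports are linear in the model
#' appraisals (identity link, unit slope on each rating's own scale) plus
#' Gaussian noise `sigma_r`, clipped to scale:
#' * `rating_belief` (0-25 yuan) tracks the second-order belief;
#' * `rating_care`, `rating_guilt`, `rating_gratitude` (0-100) track
#'   perceived care;
#' * `rating_obligation` (0-100) tracks the normalized second-order belief;
#' * `rating_indebtedness` (0-100) tracks an even blend of both appraisals.
#'
#' @param params An [agent_params()] object.
#' @param design A [make_design()] trial table.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return The design with appraisal columns (`e_second`, `omega`), the
#'   decision columns `d_b` (yuan, on-grid) and `accept` (logical), and the
#'   six rating columns.
#' @examples
#' a <- agent_params(theta = 0.1, phi = 0.6, kappa = 0.4)
#' head(simulate_agent(a, make_design("2a", seed = 1), seed = 2))
#' @export
simulate_agent <- function(params, design, seed = 1) {
  stopifnot(inherits(params, "agent_params"))
  n <- nrow(design)
  app <- appraise(design, params$kappa)

  # for acceptance-type agents the sign of phi encodes gratitude vs guilt;
  # the reciprocity utility only takes the communal weight's magnitude
  phi_recip <- if (params$decision == "acceptance") abs(params$phi) else params$phi

  with_seed(seed, {
    d_opt <- optimal_reciprocity(params$theta, phi_recip, app$e_second,
                                 app$omega, design$gamma_b, snap = FALSE)
    d_b <- snap_to_grid(clip(d_opt + stats::rnorm(n, 0, params$sigma_d),
                             0, design$gamma_b))

    uu <- acceptance_utilities(params$theta, params$phi, design$d_a,
                               design$mu, design$max_benefit,
                               app$e_second, app$omega, design$gamma_b)
    p_acc <- accept_probability(uu$u_accept, uu$u_reject, params$tau)
    # exact indifference (costless help, u = 0) resolves to accepting, so
    # the deterministic large-tau limit is well defined on every trial
    accept <- ifelse(design$choice_type == "force_accept" | p_acc == 0.5,
                     TRUE, stats::runif(n) < p_acc)

    rate100 <- function(x) clip(x + stats::rnorm(n, 0, params$sigma_r), 0, 100)
    belief_noise <- stats::rnorm(n, 0, params$sigma_r * 25 / 100)
    out <- cbind(as.data.frame(design), app)
    out$d_b <- d_b
    out$accept <- accept
    out$rating_belief <- snap_to_grid(clip(app$e_second + belief_noise, 0, 25))
    out$rating_care <- rate100(100 * app$omega)
    out$rating_guilt <- rate100(100 * app$omega)
    out$rating_gratitude <- rate100(100 * app$omega)
    out$rating_obligation <- rate100(100 * app$e_second / design$gamma_b)
    out$rating_indebtedness <-
      rate100(100 * (app$e_second / design$gamma_b + app$omega) / 2)
    out
  })
}

#' Default population prior
#'
#' Uniform ranges used by [sample_population()]. Greed is concentrated at
#' low values (most people give most of the appraisal target back), while
#' the tradeoff and intention-discount parameters span nearly their full
#' ranges, reflecting the wide individual differences the task elicits.
#'
#' @param decision `"reciprocity"` or `"acceptance"` (changes the `phi`
#'   range to the signed interval).
#' @return Named list of `c(lower, upper)` ranges.
#' @export
default_prior <- function(decision = c("reciprocity", "acceptance")) {
  decision <- match.arg(decision)
  list(
    theta = c(0, 0.35),
    phi = if (decision == "reciprocity") c(0.05, 0.95) else c(-0.9, 0.9),
    kappa = c(0.05, 0.95),
    tau = c(2, 8),
    sigma_d = c(2, 2),
    sigma_r = c(10, 10)
  )
}

#' Sample a population of agent parameter sets
#'
#' Draws `n` independent parameter sets uniformly from the ranges in
#' `prior` (degenerate ranges pin a parameter). Optionally couples `kappa`
#' with the obligation weight `1 - phi` through a shared latent uniform,
#' mimicking the empirical tendency for people sensitive to strategic
#' intent to also weight obligation.
#'
#' @param n Number of agents (>= 1).
#' @param prior Named list of `c(lower, upper)` ranges; see
#'   [default_prior()].
#' @param seed Integer seed.
#' @param decision Passed to [agent_params()].
#' @param kappa_phi_cor Mixing weight in \[0, 1\]: 0 draws `kappa` and `phi`
#'   independently; 1 makes `kappa` and `1 - phi` share one latent rank.
#' @return List of [agent_params()] objects.
#' @examples
#' pop <- sample_population(5, seed = 7)
#' sapply(pop, `[[`, "theta")
#' @export
sample_population <- function(n, prior = default_prior(decision), seed = 1,
                              decision = c("reciprocity", "acceptance"),
                              kappa_phi_cor = 0) {
  decision <- match.arg(decision)
  if (!is.numeric(n) || n < 1) stop_input("`n` must be >= 1")
  for (nm in names(prior)) {
    rg <- prior[[nm]]
    if (length(rg) != 2 || any(!is.finite(rg)) || rg[2] < rg[1]) {
      stop_input(sprintf("prior range for `%s` is invalid", nm))
    }
  }
  check_number(kappa_phi_cor, "kappa_phi_cor", 0, 1)
  draw <- function(rg, u) rg[1] + u * (rg[2] - rg[1])
  with_seed(seed, {
    u_phi <- stats::runif(n)
    u_kap <- stats::runif(n)
    # shared latent rank couples kappa with the obligation weight 1 - phi
    u_kap <- kappa_phi_cor * (1 - u_phi) + (1 - kappa_phi_cor) * u_kap
    lapply(seq_len(n), function(i) {
      agent_params(
        theta = draw(prior$theta, stats::runif(1)),
        phi = draw(prior$phi, u_phi[i]),
        kappa = draw(prior$kappa, u_kap[i]),
        tau = draw(prior$tau, stats::runif(1)),
        sigma_d = draw(prior$sigma_d, stats::runif(1)),
        sigma_r = draw(prior$sigma_r, stats::runif(1)),
        decision = decision
      )
    })
  })
}

#' Simulate a cohort
#'
#' [sample_population()] plus [simulate_agent()] for each draw, stacked into
#' one long table with a `participant` column.
#'
#' @inheritParams sample_population
#' @param study Design layout passed to [make_design()].
#' @param ... Passed to [sample_population()].
#' @return List with `params` (list of [agent_params()]) and `trials` (long
#'   data frame).
#' @export
simulate_cohort <- function(n, study = "2a", seed = 1, ...) {
  seeds <- child_seeds(seed, 2L * n + 1L)
  design <- make_design(study, seed = seeds[1])
  params <- sample_population(n, seed = seeds[2], ...)
  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    tab <- simulate_agent(params[[i]], design, seed = seeds[2 + i])
    cbind(participant = i, tab)
  }))
  list(params = params, trials = trials)
}
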
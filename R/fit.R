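# Per-participant estimation: SSE minimization for continuous reciprocity,
# maximum likelihood for binary acceptance, both by bounded quasi-Newton
# (L-BFGS-B) with seeded uniform multi-start. AIC supports model comparison.

N_RESTARTS_DEFAULT <- 20L
PROB_EPS <- 1e-9

multi_start_optim <- function(objective, lower, upper, n_restarts, seed) {
  k <- length(lower)
  starts <- with_seed(seed, matrix(stats::runif(n_restarts * k), n_restarts, k))
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")
  # clamp away from bounds so L-BFGS-B has room for finite differences
  eps <- pmax((upper - lower) * 1e-4, 1e-8)
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(n_restarts)) {
    fit <- tryCatch(
      stats::optim(clip(starts[i, ], lower + eps, upper - eps), objective,
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    better <- is.null(best) || fit$value < best$value - 1e-12 ||
      (abs(fit$value - best$value) <= 1e-12 &&
         isTRUE(all(fit$par < best$par)[which(fit$par != best$par)[1]]))
    if (better) best <- fit
  }
  if (is.null(best)) stop_input("all optimization restarts failed")
  list(par = best$par, value = best$value, converged = any_conv)
}

new_fit_result <- function(participant, model, par, objective, objective_type,
                           n_trials, aic, converged, n_restarts, seed,
                           extra = list()) {
  structure(c(list(participant = participant, model = model,
                   par = par, objective = objective,
                   objective_type = objective_type, n_trials = n_trials,
                   aic = aic, converged = converged,
                   n_restarts = n_restarts, seed = seed), extra),
            class = "fit_result")
}

#' @exportS3Method base::print
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result model %s, participant %s>\n", x$model,
              as.character(x$participant %||% NA)))
  cat("  ", paste(sprintf("%s=%.4f", names(x$par), x$par), collapse = " "), "\n")
  cat(sprintf("  %s = %.4f over %d trials; AIC = %.2f (converged: %s)\n",
              x$objective_type, x$objective, x$n_trials, x$aic, x$converged))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a reciprocity model to one participant
#'
#' Estimates the model's parameters by minimizing the sum of squared error
#' between model-predicted and observed reciprocity amounts over the
#' participant's forced-accept trials, with `n_restarts` seeded uniform
#' starting points. The objective uses the continuous clipped optimum (a
#' smooth function of the parameters); reported predictions snap to the
#' 0.1-yuan response grid. `AIC = n * log(SSE / n) + 2k`.
#'
#' @param trials One participant's trial table (a [simulate_agent()] table
#'   or a validated imported one); rows with `choice_type ==
#'   "force_accept"` and a finite `d_b` are used.
#' @param model A reciprocity [build_model()] spec (default `"1.1"`).
#' @param seed Integer seed for the restarts.
#' @param n_restarts Number of random starting points.
#' @return A `fit_result` with fields `par`, `objective` (SSE), `aic`,
#'   `predictions` (on-grid) and convergence metadata.
#' @examples
#' a <- agent_params(theta = 0.1, phi = 0.6, kappa = 0.4)
#' tab <- simulate_agent(a, make_design("2a", seed = 1), seed = 2)
#' fit_reciprocity(tab, seed = 3)
#' @export
fit_reciprocity <- function(trials, model = build_model("1.1"), seed = 1,
                            n_restarts = N_RESTARTS_DEFAULT) {
  stopifnot(inherits(model, "model_spec"))
  if (model$decision != "reciprocity") {
    stop_input("`model` must be a reciprocity model")
  }
  if (!is.null(trials$choice_type)) {
    trials <- trials[trials$choice_type == "force_accept", , drop = FALSE]
  }
  trials <- trials[is.finite(trials$d_b), , drop = FALSE]
  n <- nrow(trials)
  if (n < 8) stop_input("need at least 8 forced-accept trials with valid d_b")

  obs <- trials$d_b
  objective <- function(p) {
    names(p) <- model$par_names
    sum((obs - model$predict(p, trials))^2)
  }
  opt <- multi_start_optim(objective, model$lower, model$upper,
                           n_restarts, seed)
  par <- stats::setNames(opt$par, model$par_names)
  k <- length(par)
  sse <- opt$value
  aic <- n * log(max(sse, 1e-12) / n) + 2 * k
  preds <- snap_to_grid(model$predict(par, trials))
  new_fit_result(trials$participant[1] %||% NA, model$name, par, sse, "sse",
                 n, aic, opt$converged, n_restarts, seed,
                 extra = list(predictions = preds, observed = obs))
}

#' Fit a help-acceptance model to one participant
#'
#' Maximum-likelihood estimation of the acceptance model on free-choice
#' trials: the log-likelihood of the observed accept/reject choices under
#' the model's logistic choice probabilities is maximized by seeded
#' multi-start L-BFGS-B. `AIC = 2k - 2 logL`. If the participant made only
#' one kind of choice the fit is still returned but flagged
#' (`boundary = TRUE`), since the temperature is then unbounded.
#'
#' @param trials One participant's trial table; rows with `choice_type ==
#'   "free_choice"` and a non-missing `accept` are used.
#' @param model An acceptance [build_model()] spec (default `"2.1"`).
#' @inheritParams fit_reciprocity
#' @return A `fit_result` with `par`, `objective` (negative log-likelihood),
#'   `aic`, `p_accept`, `accuracy` (fraction of choices matched at the 0.5
#'   threshold) and a `boundary` flag.
#' @export
fit_acceptance <- function(trials, model = build_model("2.1"), seed = 1,
                           n_restarts = N_RESTARTS_DEFAULT) {
  stopifnot(inherits(model, "model_spec"))
  if (model$decision != "acceptance") {
    stop_input("`model` must be an acceptance model")
  }
  if (!is.null(trials$choice_type)) {
    trials <- trials[trials$choice_type == "free_choice", , drop = FALSE]
  }
  trials <- trials[!is.na(trials$accept), , drop = FALSE]
  n <- nrow(trials)
  if (n < 8) stop_input("need at least 8 free-choice trials with choices")
  y <- as.numeric(trials$accept)
  boundary <- length(unique(y)) < 2
  if (boundary) {
    warning("participant made only one kind of choice; fit is at a boundary",
            call. = FALSE)
  }

  objective <- function(p) {
    names(p) <- model$par_names
    pr <- clip(model$predict(p, trials), PROB_EPS, 1 - PROB_EPS)
    -sum(y * log(pr) + (1 - y) * log(1 - pr))
  }
  opt <- multi_start_optim(objective, model$lower, model$upper,
                           n_restarts, seed)
  par <- stats::setNames(opt$par, model$par_names)
  k <- length(par)
  nll <- opt$value
  pr <- model$predict(par, trials)
  new_fit_result(trials$participant[1] %||% NA, model$name, par, nll,
                 "negloglik", n, 2 * k + 2 * nll, opt$converged,
                 n_restarts, seed,
                 extra = list(p_accept = pr, observed = y,
                              accuracy = mean((pr >= 0.5) == y),
                              boundary = boundary))
}

#' Fit a model to every participant of a cohort
#'
#' @param trials Long trial table with a `participant` column.
#' @param model A [build_model()] spec; its decision type selects the
#'   fitting routine.
#' @param seed Integer seed; each participant gets a derived child seed.
#' @param n_restarts Restarts per participant.
#' @return List of `fit_result` objects, one per participant.
#' @export
fit_cohort <- function(trials, model = build_model("1.1"), seed = 1,
                       n_restarts = N_RESTARTS_DEFAULT) {
  ids <- unique(trials$participant)
  seeds <- child_seeds(seed, length(ids))
  fitter <- if (model$decision == "reciprocity") fit_reciprocity else fit_acceptance
  out <- lapply(seq_along(ids), function(i) {
    fitter(trials[trials$participant == ids[i], , drop = FALSE],
           model = model, seed = seeds[i], n_restarts = n_restarts)
  })
  names(out) <- as.character(ids)
  out
}

#' Compare fitted models by AIC
#'
#' Summarizes per-participant fits of several models: group-summed AIC,
#' mean AIC, and the number of participants for which each model attains
#' the lowest AIC. All models must cover the same participants and share a
#' decision type.
#'
#' @param fits Named list: one element per model, each a list of
#'   `fit_result` objects as returned by [fit_cohort()].
#' @return Data frame with one row per model, sorted by summed AIC.
#' @export
compare_models <- function(fits) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    stop_input("`fits` must be a named list (one element per model)")
  }
  ids <- lapply(fits, names)
  if (length(unique(lapply(ids, sort))) != 1) {
    stop_input("all models must be fitted to the same participants")
  }
  aic <- sapply(fits, function(fl) sapply(fl, `[[`, "aic"))
  aic <- matrix(aic, ncol = length(fits),
                dimnames = list(ids[[1]], names(fits)))
  best <- apply(aic, 1, function(row) colnames(aic)[which.min(row)])
  out <- data.frame(
    model = colnames(aic),
    sum_aic = colSums(aic),
    mean_aic = colMeans(aic),
    n_best = as.vector(table(factor(best, levels = colnames(aic)))),
    row.names = NULL
  )
  out[order(out$sum_aic), ]
}
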
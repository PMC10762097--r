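# Parameter recovery (simulate -> refit -> correlate) and model simulation
# over parameter grids.

#' Parameter recovery study
#'
#' Simulates each true parameter set on the design, refits the model to the
#' simulated data, and correlates recovered with true parameters: one
#' Pearson r per parameter and a pooled r computed over all parameters
#' jointly after z-scoring each parameter's true and recovered vectors by
#' the true vector's mean and SD (so parameters on different scales
#' contribute comparably).
#'
#' @param model A [build_model()] spec; its decision type selects the
#'   simulated outcome (reciprocity amounts or acceptance choices) and the
#'   fitting routine. Recovered parameters are matched to [agent_params()]
#'   fields by name, so the spec should use the canonical names
#'   (`theta`, `phi`, `kappa`, `tau`).
#' @param true_params List of at least 10 [agent_params()] objects.
#' @param design A [make_design()] trial table.
#' @param seed Integer seed covering simulation and refitting.
#' @param noise Optional named list overriding simulation noise for every
#'   agent, e.g. `list(sigma_d = 2)`; `NULL` uses each agent's own values.
#' @param n_restarts Restarts per refit.
#' @return A `recovery_report`: list with `values` (long data frame of
#'   true/recovered pairs), `per_parameter` (data frame of per-parameter r,
#'   with a `degenerate` flag where a true vector is constant), and
#'   `pooled_r`.
#' @examples
#' \donttest{
#' pop <- sample_population(12, seed = 3)
#' rep <- parameter_recovery(build_model("1.1"), pop,
#'                           make_design("2a", seed = 1), seed = 4)
#' rep$pooled_r
#' }
#' @export
parameter_recovery <- function(model, true_params, design, seed = 1,
                               noise = NULL, n_restarts = N_RESTARTS_DEFAULT) {
  stopifnot(inherits(model, "model_spec"))
  n <- length(true_params)
  if (n < 10) stop_input("need at least 10 parameter sets")
  par_names <- intersect(model$par_names,
                         c("theta", "phi", "kappa", "tau"))
  if (length(par_names) == 0) {
    stop_input("model has no canonically named parameters to recover")
  }
  seeds <- child_seeds(seed, 2L * n)
  rows <- lapply(seq_len(n), function(i) {
    p <- true_params[[i]]
    for (nm in names(noise)) p[[nm]] <- noise[[nm]]
    tab <- simulate_agent(p, design, seed = seeds[i])
    fit <- if (model$decision == "reciprocity") {
      fit_reciprocity(tab, model, seed = seeds[n + i],
                      n_restarts = n_restarts)
    } else {
      fit_acceptance(tab, model, seed = seeds[n + i],
                     n_restarts = n_restarts)
    }
    data.frame(agent = i, parameter = par_names,
               true = unlist(p[par_names]),
               recovered = fit$par[par_names], row.names = NULL)
  })
  values <- do.call(rbind, rows)

  per_par <- do.call(rbind, lapply(split(values, values$parameter), function(v) {
    degenerate <- stats::sd(v$true) == 0 || stats::sd(v$recovered) == 0
    data.frame(parameter = v$parameter[1],
               r = if (degenerate) NA_real_ else
                 stats::cor(v$true, v$recovered),
               degenerate = degenerate, row.names = NULL)
  }))
  if (any(per_par$degenerate)) {
    warning("constant parameter vector(s): ",
            paste(per_par$parameter[per_par$degenerate], collapse = ", "),
            "; their r is undefined", call. = FALSE)
  }

  zs <- lapply(split(values, values$parameter), function(v) {
    if (stats::sd(v$true) == 0) return(NULL)
    m <- mean(v$true); s <- stats::sd(v$true)
    data.frame(true = (v$true - m) / s, recovered = (v$recovered - m) / s)
  })
  pooled <- do.call(rbind, zs)
  pooled_r <- if (is.null(pooled)) NA_real_ else
    stats::cor(pooled$true, pooled$recovered)

  structure(list(values = values, per_parameter = per_par,
                 pooled_r = pooled_r, model = model$name, n = n),
            class = "recovery_report")
}

#' @exportS3Method base::print
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report model %s, %d agents> pooled r = %.3f\n",
              x$model, x$n, x$pooled_r))
  print(x$per_parameter)
  invisible(x)
}

#' Simulate predicted reciprocity over a parameter grid
#'
#' Mean model-predicted reciprocity per condition for every combination of
#' the supplied parameter values, averaged across the design's cost levels.
#' Reproduces the diverging-condition pattern: lowering `phi` (more weight
#' on obligation) raises predicted reciprocity when repayment was known to
#' be possible but lowers it when it was not, more strongly at high
#' `kappa`.
#'
#' @param theta,phi,kappa Numeric vectors of parameter values (each
#'   non-empty, within bounds).
#' @param design A [make_design()] trial table.
#' @return Data frame with columns `theta`, `phi`, `kappa`, `condition`,
#'   `mean_reciprocity`.
#' @examples
#' g <- simulate_grid(theta = 0.1, phi = c(0, 1), kappa = c(0, 1),
#'                    design = make_design("2a", seed = 1))
#' @export
simulate_grid <- function(theta, phi, kappa, design) {
  if (length(theta) == 0 || length(phi) == 0 || length(kappa) == 0) {
    stop_input("parameter ranges must be non-empty")
  }
  if (any(theta < 0 | theta > 1) || any(phi < 0 | phi > 1) ||
      any(kappa < 0 | kappa > 1)) {
    stop_input("parameter values must lie in [0, 1]")
  }
  cells <- expand.grid(theta = theta, phi = phi, kappa = kappa,
                       KEEP.OUT.ATTRS = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    app <- appraise(design, cells$kappa[i])
    d <- optimal_reciprocity(cells$theta[i], cells$phi[i], app$e_second,
                             app$omega, design$gamma_b)
    agg <- tapply(d, design$condition, mean)
    data.frame(theta = cells$theta[i], phi = cells$phi[i],
               kappa = cells$kappa[i], condition = names(agg),
               mean_reciprocity = as.vector(agg), row.names = NULL)
  })
  do.call(rbind, out)
}
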
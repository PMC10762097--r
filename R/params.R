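#' Latent preference parameters of one participant
#'
#' Bundles the latent parameters of the utility models: greed `theta`
#' (weight on self-interest), the communal-vs-obligation tradeoff `phi`,
#' the intention-discount `kappa` (how strongly the perceived strategic
#' expectation reduces perceived care), the gratitude-vs-guilt mix `delta`
#' (fixed; not identifiable from reciprocity data), the choice temperature
#' `tau` used by the help-acceptance choice rule, and simulation noise
#' scales `sigma_d` (yuan, on decisions) and `sigma_r` (rating points, on
#' 0-100 self-reports).
#'
#' For reciprocity, `phi` lies in \[0, 1\]: 1 weights communal concern
#' (matching perceived care) and 0 weights obligation (matching the
#' second-order belief). For help-acceptance `phi` is signed in \[-1, 1\]:
#' positive values express gratitude (approach), negative values guilt
#' (avoidance), and `1 - |phi|` is the residual weight on obligation.
#'
#' @param theta Greed weight in \[0, 1\].
#' @param phi Communal-vs-obligation tradeoff; \[0, 1\] for reciprocity,
#'   \[-1, 1\] when `decision = "acceptance"`.
#' @param kappa Intention discount in \[0, 1\].
#' @param delta Gratitude share of communal concern in \[0, 1\]; fixed at
#'   0.5 because gratitude and guilt push reciprocity the same way and the
#'   task cannot separate them.
#' @param tau Choice temperature (> 0), acceptance model only.
#' @param sigma_d Decision noise SD in yuan (>= 0), simulation only.
#' @param sigma_r Rating noise SD on the 0-100 scale (>= 0), simulation only.
#' @param decision `"reciprocity"` or `"acceptance"`; controls the bound
#'   checked for `phi`.
#' @return An object of class `agent_params` (a named list).
#' @examples
#' agent_params(theta = 0.1, phi = 0.6, kappa = 0.4)
#' @export
agent_params <- function(theta, phi, kappa, delta = 0.5, tau = 3,
                         sigma_d = 0, sigma_r = 0,
                         decision = c("reciprocity", "acceptance")) {
  decision <- match.arg(decision)
  check_number(theta, "theta", 0, 1)
  if (decision == "reciprocity") {
    check_number(phi, "phi", 0, 1)
  } else {
    check_number(phi, "phi", -1, 1)
  }
  check_number(kappa, "kappa", 0, 1)
  check_number(delta, "delta", 0, 1)
  check_number(tau, "tau", .Machine$double.eps, Inf)
  check_number(sigma_d, "sigma_d", 0, Inf)
  check_number(sigma_r, "sigma_r", 0, Inf)
  structure(
    list(theta = theta, phi = phi, kappa = kappa, delta = delta, tau = tau,
         sigma_d = sigma_d, sigma_r = sigma_r, decision = decision),
    class = "agent_params"
  )
}

#' @exportS3Method base::print
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "<agent_params (%s)> theta=%.3g phi=%.3g kappa=%.3g tau=%.3g sigma_d=%.3g sigma_r=%.3g\n",
    x$decision, x$theta, x$phi, x$kappa, x$tau, x$sigma_d, x$sigma_r))
  invisible(x)
}
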
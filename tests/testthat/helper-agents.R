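# Shared fixtures: deterministic agents and random parameter draws.

noiseless_agent <- function(theta, phi, kappa, decision = "reciprocity") {
  agent_params(theta = theta, phi = phi, kappa = kappa, tau = 1e6,
               sigma_d = 0, sigma_r = 0, decision = decision)
}

random_recip_draws <- function(n, seed) {
  indebtr:::with_seed(seed, data.frame(
    theta = runif(n, 0, 0.99),
    phi = runif(n),
    kappa = runif(n),
    d_a = runif(n, 0, 16),
    condition = sample(c("repayment_impossible", "repayment_possible"),
                       n, replace = TRUE)
  ))
}
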
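# Per-participant estimation, model comparison, recovery and simulation.

test_that("noiseless reciprocity data return the generating parameters", {
  d <- make_design("2a", seed = 1)
  a <- noiseless_agent(0.1, 0.6, 0.4)
  tab <- simulate_agent(a, d, seed = 2)
  fit <- fit_reciprocity(tab, seed = 3)
  expect_lt(max(abs(fit$par - c(0.1, 0.6, 0.4))), 0.05)
  expect_lt(fit$objective, 0.1)
  expect_true(fit$converged)
})

test_that("all-zero giving is explained by greed with zero error", {
  d <- make_design("2a", seed = 1)
  tab <- simulate_agent(noiseless_agent(0.9, 0.5, 0.5), d, seed = 2)
  expect_true(all(tab$d_b == 0))
  fit <- fit_reciprocity(tab, seed = 4)
  expect_lt(fit$objective, 1e-6)
  expect_true(all(fit$predictions == 0))
  # greed must be large enough to null every appraisal target
  expect_gt(fit$par[["theta"]], 0.5)
})

test_that("fits are reproducible and respect bounds", {
  d <- make_design("2a", seed = 5)
  a <- agent_params(0.2, 0.3, 0.7, sigma_d = 2, sigma_r = 10)
  tab <- simulate_agent(a, d, seed = 6)
  f1 <- fit_reciprocity(tab, seed = 11)
  f2 <- fit_reciprocity(tab, seed = 11)
  expect_identical(f1$par, f2$par)
  m <- build_model("1.1")
  expect_true(all(f1$par >= m$lower & f1$par <= m$upper))
  expect_error(fit_reciprocity(tab[1:4, ], seed = 1), "at least 8")
})

test_that("deterministic choices are reproduced perfectly by the acceptance fit", {
  d <- make_design("2a", seed = 1)
  tab <- simulate_agent(noiseless_agent(0.25, 0.55, 0.5), d, seed = 2)
  fit <- suppressWarnings(fit_acceptance(tab, seed = 3))
  expect_equal(fit$accuracy, 1)
})

test_that("an all-accept participant is flagged and fitted at the boundary", {
  d <- make_design("2a", seed = 1)
  tab <- simulate_agent(noiseless_agent(0.1, 0.9, 0.1), d, seed = 2)
  tab$accept <- TRUE
  expect_warning(fit <- fit_acceptance(tab, seed = 3), "boundary")
  expect_true(fit$boundary)
  expect_true(all(fit$p_accept >= 0.5))
})

test_that("model comparison requires matched participants and is zero for identical fits", {
  d <- make_design("2a", seed = 2)
  pop <- sample_population(4, seed = 21)
  trials <- do.call(rbind, lapply(1:4, function(i) {
    cbind(participant = i, simulate_agent(pop[[i]], d, seed = 30 + i))
  }))
  fits <- fit_cohort(trials, seed = 40)
  cmp <- compare_models(list(a = fits, b = fits))
  expect_equal(diff(cmp$sum_aic), 0)
  fits_sub <- fits[1:3]
  expect_error(compare_models(list(a = fits, b = fits_sub)), "same participants")
})

test_that("noise-free recovery is essentially perfect", {
  pop <- lapply(1:10, function(i) {
    indebtr:::with_seed(i, noiseless_agent(runif(1, 0, 0.3), runif(1, 0.1, 0.9),
                                           runif(1, 0.1, 0.9)))
  })
  rep <- parameter_recovery(build_model("1.1"), pop, make_design("2a", seed = 1),
                            seed = 2)
  expect_gt(rep$pooled_r, 0.99)
  expect_true(all(rep$per_parameter$r > 0.99))
})

test_that("recovery flags degenerate true vectors", {
  pr <- default_prior()
  pr$theta <- c(0.2, 0.2)
  pop <- sample_population(10, prior = pr, seed = 5)
  expect_warning(
    rep <- parameter_recovery(build_model("1.1"), pop,
                              make_design("2a", seed = 1), seed = 2),
    "constant")
  expect_true(is.na(rep$per_parameter$r[rep$per_parameter$parameter == "theta"]))
})

test_that("a generated kappa-obligation association survives the fit", {
  pop <- sample_population(25, seed = 8, kappa_phi_cor = 0.9)
  rep <- parameter_recovery(build_model("1.1"), pop,
                            make_design("2a", seed = 3), seed = 9,
                            noise = list(sigma_d = 1))
  v <- rep$values
  kap <- v$recovered[v$parameter == "kappa"]
  phi <- v$recovered[v$parameter == "phi"]
  expect_gt(cor(kap, 1 - phi), 0.5)
})

test_that("grid simulation reproduces the diverging condition pattern", {
  g <- simulate_grid(theta = c(0.1, 1), phi = c(0, 0.5, 1), kappa = c(0, 1),
                     design = make_design("2a", seed = 1))
  # total greed gives nothing back anywhere
  expect_true(all(g$mean_reciprocity[g$theta == 1] == 0))
  # at high kappa, more obligation (lower phi) raises repayment-possible
  # giving and lowers repayment-impossible giving
  hk <- g[g$theta == 0.1 & g$kappa == 1, ]
  poss <- hk[hk$condition == "repayment_possible", ]
  imp <- hk[hk$condition == "repayment_impossible", ]
  expect_true(all(diff(poss$mean_reciprocity[order(poss$phi)]) < 0))
  expect_true(all(diff(imp$mean_reciprocity[order(imp$phi)]) > 0))
  expect_error(simulate_grid(numeric(0), 0.5, 0.5, make_design("2a", seed = 1)),
               "non-empty")
})
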
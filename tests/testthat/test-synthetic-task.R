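# Task designs and the generative agent model.

test_that("designs have the layout of each study variant", {
  d2a <- make_design("2a", seed = 1)
  expect_equal(nrow(d2a), 48)
  expect_equal(as.vector(table(d2a$condition)), c(24L, 24L))
  tab <- table(d2a$condition, d2a$choice_type)
  expect_true(all(tab == 12))
  expect_true(all(d2a$mu == 1))

  d2b <- make_design("2b", seed = 1)
  expect_equal(nrow(d2b), 56)
  expect_equal(as.vector(table(d2b$condition)), c(28L, 28L))
  expect_true(length(unique(d2b$mu)) > 1)

  dfm <- make_design("fmri", seed = 1)
  expect_equal(nrow(dfm), 48)
  expect_true(all(dfm$choice_type == "force_accept"))

  expect_error(make_design("study9"), "arg")
})

test_that("designs respect the endowment and pain-reduction constraints", {
  for (study in c("2a", "2b", "fmri")) {
    d <- make_design(study, seed = 5)
    expect_true(all(d$d_a >= 0 & d$d_a <= d$gamma_a))
    expect_true(all(d$gamma_b > d$gamma_a))
    expect_true(all(d$d_a * d$mu <= 16))
    expect_true(all(d$max_benefit <= 16))
  }
})

test_that("the same seed reproduces the same design and simulation", {
  expect_identical(make_design("2a", seed = 9), make_design("2a", seed = 9))
  a <- agent_params(0.2, 0.5, 0.3, sigma_d = 2, sigma_r = 10)
  d <- make_design("2a", seed = 9)
  expect_identical(simulate_agent(a, d, seed = 4), simulate_agent(a, d, seed = 4))
})

test_that("simulated decisions live on the response grid and forced trials accept", {
  a <- agent_params(0.15, 0.4, 0.6, sigma_d = 3, sigma_r = 15)
  tab <- simulate_agent(a, make_design("2a", seed = 2), seed = 7)
  expect_true(all(abs(tab$d_b - round(tab$d_b * 10) / 10) < 1e-9))
  expect_true(all(tab$d_b >= 0 & tab$d_b <= tab$gamma_b))
  expect_true(all(tab$accept[tab$choice_type == "force_accept"]))
  for (rc in c("rating_care", "rating_guilt", "rating_gratitude",
               "rating_obligation", "rating_indebtedness")) {
    expect_true(all(tab[[rc]] >= 0 & tab[[rc]] <= 100))
  }
  expect_true(all(tab$rating_belief >= 0 & tab$rating_belief <= 25))
})

test_that("noise-free agents reproduce the deterministic optimum on every trial", {
  d <- make_design("2a", seed = 3)
  draws <- random_recip_draws(10, seed = 13)
  for (i in seq_len(nrow(draws))) {
    a <- noiseless_agent(draws$theta[i], draws$phi[i], draws$kappa[i])
    tab <- simulate_agent(a, d, seed = i)
    app <- appraise(d, a$kappa)
    expect_equal(tab$d_b,
                 optimal_reciprocity(a$theta, a$phi, app$e_second, app$omega,
                                     d$gamma_b))
    # deterministic choice rule: accept iff accepting is (weakly) preferred
    uu <- acceptance_utilities(a$theta, a$phi, d$d_a, d$mu, d$max_benefit,
                               app$e_second, app$omega, d$gamma_b)
    free <- d$choice_type == "free_choice"
    expect_equal(tab$accept[free], uu$u_accept[free] >= 0)
  }
})

test_that("spec agents produce the hand-derived decisions", {
  d <- data.frame(trial_id = 1:2,
                  condition = c("repayment_impossible", "repayment_possible"),
                  choice_type = "force_accept", d_a = 10, mu = 1,
                  gamma_a = 20, gamma_b = 25, max_benefit = 16)
  tab <- simulate_agent(noiseless_agent(0, 1, 0), d, seed = 1)
  expect_equal(tab$d_b[1], 12.5)  # communal target omega * gamma_b
  tab <- simulate_agent(noiseless_agent(0, 0, 0), d, seed = 1)
  expect_equal(tab$d_b[2], 10)    # obligation target e_second
  tab <- simulate_agent(noiseless_agent(1, 0.5, 0.5), d, seed = 1)
  expect_true(all(tab$d_b == 0))  # pure greed
})

test_that("population sampling honors ranges, degenerate priors and seeding", {
  pop <- sample_population(108, seed = 7)
  expect_length(pop, 108)
  th <- sapply(pop, `[[`, "theta")
  ph <- sapply(pop, `[[`, "phi")
  kp <- sapply(pop, `[[`, "kappa")
  expect_true(all(th >= 0 & th <= 1 & ph >= 0 & ph <= 1 & kp >= 0 & kp <= 1))

  pr <- default_prior()
  pr$theta <- c(0.2, 0.2)
  fixed <- sample_population(20, prior = pr, seed = 1)
  expect_true(all(sapply(fixed, `[[`, "theta") == 0.2))

  expect_identical(sample_population(10, seed = 5), sample_population(10, seed = 5))
  bad <- default_prior(); bad$phi <- c(0.9, 0.1)
  expect_error(sample_population(5, prior = bad), "invalid")
})

test_that("kappa couples to the obligation weight when requested", {
  pop <- sample_population(200, seed = 3, kappa_phi_cor = 1)
  kp <- sapply(pop, `[[`, "kappa")
  ph <- sapply(pop, `[[`, "phi")
  expect_gt(cor(kp, 1 - ph), 0.95)
})
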
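# Pattern synthesis, cross-validated pattern regression, the neural utility
# refit, and the pattern-alignment statistic.

sim_neural_tab <- function(theta = 0.15, phi = 0.6, kappa = 0.4, seed = 1) {
  a <- agent_params(theta, phi, kappa, sigma_d = 1, sigma_r = 5)
  simulate_agent(a, make_design("fmri", seed = seed), seed = seed + 1)
}

test_that("patterns embed the appraisals along orthogonal encodings", {
  tab <- sim_neural_tab(seed = 3)
  pat <- synth_patterns(tab, v = 60, snr = 1e6, seed = 4)
  expect_equal(dim(pat$patterns), c(48, 60))
  expect_lt(abs(sum(pat$encoding$communal * pat$encoding$obligation)), 1e-10)
  # in the noiseless limit the pattern projects back to the appraisals
  proj_om <- pat$patterns %*% pat$encoding$communal
  expect_gt(cor(proj_om, tab$omega), 0.999)
  expect_error(synth_patterns(tab, v = 5), "at least 10")
})

test_that("pattern regression predicts noiseless targets almost perfectly", {
  tab <- sim_neural_tab(seed = 5)
  pat <- synth_patterns(tab, v = 60, snr = 1e6, seed = 6)
  m <- train_pattern_model(pat$patterns, tab$omega, seed = 7)
  expect_gt(m$cv_r, 0.99)
  expect_length(m$weights, 60)
})

test_that("cross-validation folds partition trials and never self-predict", {
  tab <- sim_neural_tab(seed = 8)
  pat <- synth_patterns(tab, v = 40, snr = 0.5, seed = 9)
  m <- train_pattern_model(pat$patterns, tab$omega, folds = 5, seed = 10)
  expect_equal(sort(unique(m$fold)), 1:5)
  expect_equal(length(m$fold), 48)
  # a trial's own target must not influence its prediction: corrupting the
  # targets of fold-1 trials leaves fold-1 predictions untouched (they are
  # produced by the model trained on the other folds)
  y2 <- tab$omega
  y2[m$fold == 1] <- y2[m$fold == 1] + 100
  m2 <- train_pattern_model(pat$patterns, y2, folds = 5, seed = 10)
  expect_equal(m$cv_pred[m$fold == 1], m2$cv_pred[m2$fold == 1])
})

test_that("permuted targets yield a null prediction distribution around zero", {
  tab <- sim_neural_tab(seed = 11)
  pat <- synth_patterns(tab, v = 40, snr = 0.5, seed = 12)
  rs <- indebtr:::with_seed(13, replicate(20, {
    train_pattern_model(pat$patterns, sample(tab$omega), seed = 14)$cv_r
  }))
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("maps trained on independent encodings are spatially uncorrelated", {
  cors <- sapply(1:8, function(i) {
    tab <- sim_neural_tab(seed = 20 + i)
    pat <- synth_patterns(tab, v = 100, snr = 0.5, seed = 40 + i)
    mc <- train_pattern_model(pat$patterns, tab$omega, seed = 60 + i)
    mo <- train_pattern_model(pat$patterns, tab$e_second, seed = 80 + i)
    cor(mc$weights, mo$weights)
  })
  expect_lt(abs(mean(cors)), 0.2)
})

test_that("noiseless patterns give back the behavioral tradeoff parameter", {
  theta <- 0.12; phi <- 0.65; kappa <- 0.35
  a <- agent_params(theta, phi, kappa, sigma_d = 0, sigma_r = 0, tau = 1e6)
  tab <- simulate_agent(a, make_design("fmri", seed = 31), seed = 32)
  pat <- synth_patterns(tab, v = 60, snr = 1e6, seed = 33)
  mc <- train_pattern_model(pat$patterns, tab$omega, seed = 34)
  mo <- train_pattern_model(pat$patterns, tab$e_second, seed = 35)
  fit <- fit_neural_utility(mc$cv_pred, mo$cv_pred, tab$d_b, seed = 36)
  behav <- fit_reciprocity(tab, seed = 37)
  expect_lt(abs(fit$par[["phi"]] - behav$par[["phi"]]), 0.05)
  expect_lt(abs(fit$par[["phi"]] - phi), 0.05)
  expect_gt(fit$pred_r, 0.99)
})

test_that("pure-noise patterns carry no predictive signal", {
  rs <- sapply(1:6, function(i) {
    tab <- sim_neural_tab(seed = 40 + i)
    pat <- synth_patterns(tab, v = 60, snr = 0, seed = 50 + i)
    mc <- train_pattern_model(pat$patterns, tab$omega, seed = 60 + i)
    mo <- train_pattern_model(pat$patterns, tab$e_second, seed = 70 + i)
    fit_neural_utility(mc$cv_pred, mo$cv_pred, tab$d_b, seed = 80 + i)$pred_r
  })
  expect_lt(abs(mean(rs)), 0.2)
})

test_that("the pattern-alignment statistic behaves as a correlation difference", {
  set.seed(91)
  obl <- rnorm(100)
  com <- rnorm(100)
  expect_equal(relative_pattern_similarity(com, obl, obl),
               1 - cor(com, obl))
  expect_equal(relative_pattern_similarity(obl, obl, obl), 0)
  # invariant to positive rescaling of any map
  expect_equal(relative_pattern_similarity(3 * com, obl, 0.1 * obl),
               relative_pattern_similarity(com, 7 * obl, obl))
  expect_error(relative_pattern_similarity(rep(1, 10), rnorm(10), rnorm(10)),
               "variance")
})

test_that("the permutation test is seeded and degenerate for a shared phi", {
  co <- run_neural_cohort(12, v = 60, snr = 0.5, seed = 101)
  p1 <- phi_permutation_test(co$fits, n_perm = 200, seed = 5)
  p2 <- phi_permutation_test(co$fits, n_perm = 200, seed = 5)
  expect_identical(p1$p_value, p2$p_value)
  # constant phi across participants: shuffling changes nothing
  fits_const <- lapply(co$fits, function(f) {
    f$par[["phi"]] <- 0.5
    base <- indebtr:::predict_neural_reciprocity(f$par[["theta"]], 0.5,
                                                 f$omega_hat, f$e2_hat,
                                                 f$gamma_b)
    f$pred_r <- if (sd(base) == 0) 0 else cor(base, f$observed)
    f
  })
  pc <- phi_permutation_test(fits_const, n_perm = 100, seed = 6)
  expect_equal(pc$p_value, 1)
  expect_warning(phi_permutation_test(co$fits, n_perm = 50, seed = 1), "coarse")
})
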
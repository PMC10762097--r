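# Neural utility pipeline on synthetic activity patterns: per-participant
# principal-components regression predicting the appraisal terms, their
# substitution into the reciprocity utility, a permutation test of the
# fitted tradeoff parameter, and the pattern-alignment statistic.

NEURAL_V_DEFAULT <- 200L
NEURAL_SNR_DEFAULT <- 0.11

#' Synthesize trial-wise activity patterns for one participant
#'
#' Emulates outcome-period multivoxel activity encoding the two appraisals:
#' two fixed orthonormalized ground-truth encoding maps are drawn per
#' participant, the trial signal is `omega * map1 + (e_second / gamma_b) *
#' map2`, and the observed pattern is the signal scaled to root-mean-square
#' amplitude `snr` plus unit Gaussian noise, so `snr` is the per-feature
#' signal-to-noise amplitude ratio (`snr = 0` gives pure noise). No spatial
#' structure is modeled: only the pattern algebra matters downstream.
#'
#' @param trials One participant's trial table with `omega`, `e_second`,
#'   `gamma_b` columns (see [simulate_agent()]).
#' @param v Number of features (>= 10).
#' @param snr Signal-to-noise amplitude ratio (>= 0).
#' @param seed Integer seed.
#' @return List with `patterns` (trials x `v` matrix) and `encoding`
#'   (list of the two true maps).
#' @export
synth_patterns <- function(trials, v = NEURAL_V_DEFAULT,
                           snr = NEURAL_SNR_DEFAULT, seed = 1) {
  if (v < 10) stop_input("`v` must be at least 10")
  if (snr < 0) stop_input("`snr` must be non-negative")
  n <- nrow(trials)
  with_seed(seed, {
    m1 <- stats::rnorm(v)
    m2 <- stats::rnorm(v)
    m1 <- m1 / sqrt(sum(m1^2))
    m2 <- m2 - sum(m2 * m1) * m1
    m2 <- m2 / sqrt(sum(m2^2))
    signal <- outer(trials$omega, m1) +
      outer(trials$e_second / trials$gamma_b, m2)
    rms <- stats::sd(as.vector(signal))
    scaled <- if (rms > 0) snr * signal / rms else signal * 0
    x <- scaled + matrix(stats::rnorm(n * v), n, v)
    list(patterns = x, encoding = list(communal = m1, obligation = m2))
  })
}

#' Train a cross-validated pattern-regression model
#'
#' Principal-components regression with k-fold cross-validation: within
#' each training fold the patterns are centered and projected onto
#' principal components retaining at least `var_explained` of the variance,
#' the target is regressed on the component scores, and the held-out trials
#' are predicted. The reported `cv_r` is the Pearson correlation between
#' the concatenated held-out predictions and the targets. The returned
#' weight map is the refit on all trials (back-projected to feature space).
#'
#' @param patterns Trials x features matrix.
#' @param targets Numeric target per trial (finite, non-constant).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @param var_explained Fraction of variance the retained components must
#'   reach (default 0.9).
#' @return A `pattern_model`: list with `weights` (feature vector),
#'   `intercept`, `fold` (trial fold assignment), `cv_pred`, `cv_r` and
#'   `cv_z` (Fisher z of `cv_r`).
#' @export
train_pattern_model <- function(patterns, targets, folds = 5, seed = 1,
                                var_explained = 0.9) {
  n <- nrow(patterns)
  if (n < 20) stop_input("need at least 20 trials")
  if (any(!is.finite(targets)) || stats::sd(targets) == 0) {
    stop_input("`targets` must be finite with nonzero variance")
  }
  fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))

  pcr_fit <- function(x, y) {
    ctr <- colMeans(x)
    xc <- sweep(x, 2, ctr)
    pc <- stats::prcomp(xc, center = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    k <- which(cum >= var_explained)[1]
    scores <- pc$x[, seq_len(k), drop = FALSE]
    beta <- stats::coef(stats::lm.fit(cbind(1, scores), y))
    w <- pc$rotation[, seq_len(k), drop = FALSE] %*% beta[-1]
    list(weights = as.vector(w), intercept = beta[1] - sum(ctr * w))
  }

  cv_pred <- numeric(n)
  for (f in seq_len(folds)) {
    test <- fold == f
    m <- pcr_fit(patterns[!test, , drop = FALSE], targets[!test])
    cv_pred[test] <- patterns[test, , drop = FALSE] %*% m$weights + m$intercept
  }
  cv_r <- if (stats::sd(cv_pred) == 0) 0 else stats::cor(cv_pred, targets)
  full <- pcr_fit(patterns, targets)
  structure(list(weights = full$weights, intercept = full$intercept,
                 fold = fold, cv_pred = cv_pred, cv_r = cv_r,
                 cv_z = atanh(clip(cv_r, -1 + 1e-12, 1 - 1e-12))),
            class = "pattern_model")
}

neural_pull <- function(theta, gamma_b) {
  ifelse(theta >= 1, Inf, theta * gamma_b / (2 * (1 - theta)))
}

predict_neural_reciprocity <- function(theta, phi, omega_hat, e2_hat,
                                       gamma_b) {
  d <- phi * omega_hat * gamma_b + (1 - phi) * e2_hat -
    neural_pull(theta, gamma_b)
  d[!is.finite(d)] <- 0
  clip(d, 0, gamma_b)
}

#' Fit the neural utility model for one participant
#'
#' Refits the reciprocity utility with brain-predicted appraisals in place
#' of the model appraisals: cross-validated pattern predictions of
#' perceived care and of the second-order belief enter the utility, and
#' `(theta, phi)` are estimated by SSE against the observed reciprocity
#' amounts (same multi-start procedure as [fit_reciprocity()]).
#'
#' @param omega_hat Pattern-predicted perceived care per trial (fraction).
#' @param e2_hat Pattern-predicted second-order belief per trial (yuan).
#' @param d_b Observed reciprocity amounts (yuan).
#' @param gamma_b Participant endowment (yuan). Default 25.
#' @param seed,n_restarts Multi-start controls.
#' @return A `fit_result` with `par` (`theta`, `phi`), `predictions`, the
#'   prediction correlation `pred_r`, and `aic`.
#' @export
fit_neural_utility <- function(omega_hat, e2_hat, d_b, gamma_b = 25,
                               seed = 1, n_restarts = N_RESTARTS_DEFAULT) {
  stopifnot(length(omega_hat) == length(d_b),
            length(e2_hat) == length(d_b))
  n <- length(d_b)
  objective <- function(p) {
    sum((d_b - predict_neural_reciprocity(p[1], p[2], omega_hat, e2_hat,
                                          gamma_b))^2)
  }
  opt <- multi_start_optim(objective, lower = c(0, 0), upper = c(1, 1),
                           n_restarts = n_restarts, seed = seed)
  par <- stats::setNames(opt$par, c("theta", "phi"))
  preds <- predict_neural_reciprocity(par[1], par[2], omega_hat, e2_hat,
                                      gamma_b)
  pred_r <- if (stats::sd(preds) == 0 || stats::sd(d_b) == 0) 0 else
    stats::cor(preds, d_b)
  aic <- n * log(max(opt$value, 1e-12) / n) + 2 * 2
  new_fit_result(NA, "neural", par, opt$value, "sse", n, aic,
                 opt$converged, n_restarts, seed,
                 extra = list(predictions = preds, pred_r = pred_r,
                              omega_hat = omega_hat, e2_hat = e2_hat,
                              observed = d_b, gamma_b = gamma_b))
}

#' Permutation test of the fitted tradeoff parameter
#'
#' Tests whether participant-specific `phi` estimates carry individual
#' information: the observed statistic is the mean prediction correlation
#' of the neural utility fits; the null distribution re-predicts every
#' participant's behavior with their own `theta` but a `phi` drawn by
#' permuting the fitted `phi` values across participants. The p-value is
#' the fraction of null means at or above the observed mean.
#'
#' @param neural_fits List of [fit_neural_utility()] results (>= 10).
#' @param n_perm Number of permutations (default 5000; < 100 warns).
#' @param seed Integer seed.
#' @return List with `p_value`, `observed` (mean prediction r) and `null`
#'   (vector of permuted means).
#' @export
phi_permutation_test <- function(neural_fits, n_perm = 5000, seed = 1) {
  n <- length(neural_fits)
  if (n < 10) stop_input("need at least 10 participants")
  if (n_perm < 100) {
    warning("fewer than 100 permutations gives a coarse p-value",
            call. = FALSE)
  }
  phis <- vapply(neural_fits, function(f) f$par[["phi"]], numeric(1))
  observed <- mean(vapply(neural_fits, `[[`, numeric(1), "pred_r"))

  perm_idx <- with_seed(seed,
    replicate(n_perm, sample.int(n), simplify = FALSE))
  phi_mat <- vapply(perm_idx, function(ix) phis[ix], numeric(n)) # n x n_perm

  r_mat <- vapply(seq_len(n), function(i) {
    f <- neural_fits[[i]]
    gb <- f$gamma_b
    base <- f$e2_hat - neural_pull(f$par[["theta"]], gb)
    slope <- f$omega_hat * gb - f$e2_hat
    preds <- clip(outer(slope, phi_mat[i, ]) + base, 0, gb)
    keep <- apply(preds, 2, stats::sd) > 0
    r <- numeric(n_perm)
    if (any(keep)) {
      r[keep] <- as.vector(stats::cor(f$observed, preds[, keep, drop = FALSE]))
    }
    r
  }, numeric(n_perm)) # n_perm x n
  null <- rowMeans(r_mat)
  list(p_value = mean(null >= observed), observed = observed, null = null)
}

#' Relative pattern similarity
#'
#' Difference in spatial alignment of the obligation and communal weight
#' maps with the reciprocity weight map:
#' `corr(obligation, reciprocity) - corr(communal, reciprocity)`. Positive
#' values mean the reciprocity pattern resembles the obligation pattern
#' more than the communal one. Invariant to positive rescaling of any map;
#' lies in \[-2, 2\].
#'
#' @param communal_map,obligation_map,reciprocity_map Feature-space weight
#'   vectors of equal length (e.g. from [train_pattern_model()]).
#' @return Scalar statistic.
#' @export
relative_pattern_similarity <- function(communal_map, obligation_map,
                                        reciprocity_map) {
  stopifnot(length(communal_map) == length(reciprocity_map),
            length(obligation_map) == length(reciprocity_map))
  if (stats::sd(communal_map) == 0 || stats::sd(obligation_map) == 0 ||
      stats::sd(reciprocity_map) == 0) {
    stop_input("weight maps must have nonzero variance")
  }
  stats::cor(obligation_map, reciprocity_map) -
    stats::cor(communal_map, reciprocity_map)
}

#' Run the full neural-utility pipeline on a synthetic cohort
#'
#' Simulates agents on the scanner layout, synthesizes activity patterns
#' encoding their appraisals, trains cross-validated pattern models for
#' perceived care, second-order belief and reciprocity, fits the neural
#' utility model from the pattern predictions, and computes the
#' pattern-alignment statistic per participant.
#'
#' @param n Number of participants.
#' @param v Features per pattern.
#' @param snr Signal-to-noise amplitude ratio for [synth_patterns()].
#' @param seed Integer seed.
#' @param study Design layout (default `"fmri"`).
#' @param folds CV folds.
#' @return List with `participants` (one summary row each: true and neural
#'   parameters, CV correlations, prediction r, AIC, pattern similarity)
#'   and `fits` (the [fit_neural_utility()] objects, for
#'   [phi_permutation_test()]).
#' @export
run_neural_cohort <- function(n, v = NEURAL_V_DEFAULT,
                              snr = NEURAL_SNR_DEFAULT, seed = 1,
                              study = "fmri", folds = 5) {
  co <- simulate_cohort(n, study = study, seed = seed)
  seeds <- child_seeds(seed + 1L, 5L * n)
  fits <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tab <- co$trials[co$trials$participant == i, , drop = FALSE]
    pat <- synth_patterns(tab, v = v, snr = snr, seed = seeds[i])
    m_com <- train_pattern_model(pat$patterns, tab$omega,
                                 folds = folds, seed = seeds[n + i])
    m_obl <- train_pattern_model(pat$patterns, tab$e_second,
                                 folds = folds, seed = seeds[2 * n + i])
    m_rec <- train_pattern_model(pat$patterns, tab$d_b,
                                 folds = folds, seed = seeds[3 * n + i])
    fit <- fit_neural_utility(m_com$cv_pred, m_obl$cv_pred, tab$d_b,
                              gamma_b = tab$gamma_b[1],
                              seed = seeds[4 * n + i])
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      participant = i,
      theta_true = co$params[[i]]$theta,
      phi_true = co$params[[i]]$phi,
      kappa_true = co$params[[i]]$kappa,
      theta_neural = fit$par[["theta"]],
      phi_neural = fit$par[["phi"]],
      cv_r_communal = m_com$cv_r,
      cv_r_obligation = m_obl$cv_r,
      cv_r_reciprocity = m_rec$cv_r,
      map_cor_com_obl = stats::cor(m_com$weights, m_obl$weights),
      pattern_similarity = relative_pattern_similarity(
        m_com$weights, m_obl$weights, m_rec$weights),
      pred_r = fit$pred_r,
      aic = fit$aic
    )
  }
  list(participants = do.call(rbind, rows), fits = fits)
}
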
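---
title: "Modeling indebtedness: appraisals, utilities, and neural substitution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling indebtedness: appraisals, utilities, and neural substitution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indebtr)
```

## The task and the appraisals

The models in this package describe a beneficiary in a one-shot helping
game. A benefactor with endowment $\gamma_A$ (20 yuan) spends $D_A$ to
reduce the beneficiary's pain; the beneficiary, holding a larger endowment
$\gamma_B$ (25 yuan), then chooses how much to return, $D_B$, on a
0.1-yuan grid, and — on free-choice trials — whether to accept the help at
all. The key manipulation is what the benefactor *knew*: in the
repayment-possible condition the benefactor was aware the beneficiary
could repay; in the repayment-impossible condition they believed repayment
was impossible.

Two appraisals mediate everything downstream:

- the **second-order belief** $E''$, the beneficiary's belief about the
  expected repayment — zero when the benefactor could not expect
  repayment, and equal to the cost $D_A$ when they could;
- **perceived care** $\omega = (D_A - \kappa E'')/\gamma_A$, the altruistic
  intent read into the favor. The discount $\kappa \in [0,1]$ captures how
  much a strategic expectation undercuts perceived care. Because $E''$
  equals either $0$ or $D_A$, $\omega$ stays in $[0,1]$ for any
  $\kappa \in [0,1]$, and the across-trial correlation between $\omega$
  and $E''$ flips sign as $\kappa$ moves from 0 (positive) to 1
  (negative) — a regime property the test suite checks exactly.

## Reciprocity utility

The reciprocity decision maximizes

$$U(D_B) = \theta \frac{\gamma_B - D_B}{\gamma_B}
 - (1-\theta)\left[\phi\left(\frac{\omega\gamma_B - D_B}{\gamma_B}\right)^2
 + (1-\phi)\left(\frac{E'' - D_B}{\gamma_B}\right)^2\right].$$

Greed $\theta \in [0,1]$ weights money kept; $\phi \in [0,1]$ trades off
communal concern (a quadratic pull toward the care-proportional target
$\omega\gamma_B$) against obligation (a pull toward the expected repayment
$E''$). Communal concern is itself a mixture of gratitude and guilt with
mixing weight $\delta$; because both components pull reciprocity the same
way, $\delta$ is not identifiable from this task and is fixed at 0.5, so
the communal term collapses to a single quadratic.

For $\theta < 1$ the utility is strictly concave in $D_B$ with
unconstrained maximizer

$$D^* = \phi\,\omega\gamma_B + (1-\phi)E'' -
  \frac{\theta\,\gamma_B}{2(1-\theta)},$$

clipped to $[0, \gamma_B]$ and snapped to the response grid. The grid is
the behavioral contract — `grid_optimal_reciprocity()` is the package's
independent brute-force reference, and a property test checks the closed
form against it on $10^4$ random parameter draws to within half a grid
step. At $\theta = 1$ the closed form diverges; the optimum is defined as
0 (pure self-interest keeps everything).

## Help-acceptance utility

Accepting help yields

$$U(\text{accept}) = \theta\,\frac{D_A\mu}{\max(D_A\mu)} +
 (1-\theta)\left[\phi\,\omega - (1-|\phi|)\frac{E''}{\gamma_B}\right],
 \qquad U(\text{reject}) = 0,$$

with $\mu$ the help efficiency (seconds of pain relief per yuan) and
$\max(D_A\mu)$ the design-wide maximum benefit (capped at 16 s). Here
$\phi$ is signed: $\phi > 0$ expresses gratitude (care motivates
accepting), $\phi < 0$ guilt (care motivates refusing), and $1 - |\phi|$
weights obligation, which always opposes acceptance. Rejecting leaves the
beneficiary's feelings unchanged, hence the zero utility.

The choice rule is a documented assumption: a logistic over the utility
difference with temperature $\tau > 0$,
$P(\text{accept}) = 1/(1 + e^{-\tau(U_a - U_r)})$. The source account fits
choice likelihoods without printing its link function; the logistic with a
single temperature is the standard discrete-choice rule and gives the
acceptance model four parameters $(\theta, \phi, \kappa, \tau)$. At exact
indifference ($U_a = 0$, which occurs structurally on zero-cost trials)
the simulator resolves to accepting, so the deterministic large-$\tau$
limit is well defined on every trial.

## The alternative-model family

`build_model()` exposes the comparison family behind one interface:
linear (absolute-difference) penalties (1.2), communal-only and
obligation-only restrictions (1.3, 1.4), separate unnormalized weights on
the three motives with and without the intention discount (1.5, 1.6),
tit-for-tat — a proportional return target with one slope (1.7) — and a
symmetric quadratic inequity penalty on the post-transfer payoff gap
(1.8); acceptance variants 2.2–2.5 mirror the restrictions. The exact
supplementary equations behind these comparison models were not available,
so the implementations follow their one-line descriptions plus standard
formulations; two open choices were resolved and documented here rather
than guessed silently: the separate-weight models do **not** normalize
their weights to sum to one, and the inequity penalty is symmetric (no
advantageous/disadvantageous asymmetry). All these interpretations are
isolated in one file and behave as exact restrictions where they should:
the tests verify that 1.3 and 1.4 can never beat 1.1 on raw SSE and that
AIC recovers the generating model from its own data.

## Estimation

Fitting is per participant. Reciprocity models minimize the sum of squared
error between predicted and observed amounts on forced-accept trials;
acceptance models maximize the Bernoulli log-likelihood on free-choice
trials. Both use bounded quasi-Newton (L-BFGS-B) from 20 seeded uniform
starting points, which guards against the non-convex coupling between
$\kappa$ and $\phi$; ties between restarts break toward the lower
objective, then the lexicographically smaller parameter vector. The SSE
objective uses the *continuous* clipped optimum so the surface is smooth;
reported predictions are grid-snapped. AIC is $n\ln(\mathrm{SSE}/n) + 2k$
for SSE fits and $2k - 2\log L$ for likelihood fits, with the SSE floored
at $10^{-12}$ to keep noiseless fits finite. Choice probabilities are
clamped to $[10^{-9}, 1-10^{-9}]$; a participant with only one kind of
choice is fitted but flagged (`boundary = TRUE`), since the temperature is
then unbounded.

Two degeneracies deserve note. First, all-zero giving is explained
perfectly by any sufficiently greedy parameter vector, so $\phi$ and
$\kappa$ are unidentifiable for such agents — the self-consistency tests
therefore condition on informative data (nonzero decisions in both
intention conditions), a check made from the data alone. Second, recovery
reports flag constant true-parameter vectors, whose correlation is
undefined.

`parameter_recovery()` simulates from known parameters, refits, and
reports per-parameter Pearson correlations plus a pooled correlation over
all parameters jointly (each parameter z-scored by its true mean and SD).
When no empirical noise estimate is available the default decision noise
is $\sigma_D = 2$ yuan, a realistic trial-to-trial jitter of roughly one
grid decade on a 25-yuan scale.

## The synthetic generator

`make_design()` reproduces the three layouts: 48 trials (24 per condition,
half forced / half free) with $\mu = 1$; 56 trials with
$\mu \in \{0.5, 1, 1.5\}$ subject to the 16-second relief cap; and a
48-trial all-forced scanner variant. The exact pre-determined benefactor
cost schedule was published only in supplementary material, so costs
default to the even grid $\{0, 2, \dots, 16\}$ yuan spanning the plotted
range, and the efficiency levels are symmetric around 1; both are
configurable. Decision noise is Gaussian on the utility optimum, censored
at the endowment bounds and grid-snapped. Self-reports are linear in the
model appraisals on each rating's own scale with unit slope and Gaussian
noise ($\sigma_R = 10$ rating points by default), so linkage regressions
have a known generative slope for testing. Population draws are uniform
within ranges; greed concentrates low ($\theta \le 0.35$) because most
people return most of the appraisal target, while $\phi$ and $\kappa$ span
nearly their full ranges. An optional `kappa_phi_cor` couples $\kappa$
with the obligation weight $1-\phi$ through a shared latent rank,
emulating the empirical tendency for intention-sensitive people to weight
obligation; the default draws them independently.

What the generator does *not* emulate: sequential or learning effects
across trials, response times, asymmetric or heavy-tailed decision noise,
rating drift between the task and the recall session, and any spatial
structure in the synthetic activity patterns. Passing tests on this
generator therefore demonstrate internal consistency of the estimation
machinery under the stated noise model, not robustness to the full
messiness of real data.

## Neural utility pipeline

`synth_patterns()` embeds the two appraisals along two orthonormalized
random encoding maps over $V = 200$ features:
signal$_t = \omega_t \vec m_1 + (E''_t/\gamma_B)\,\vec m_2$, scaled to a
root-mean-square amplitude equal to `snr` and added to unit Gaussian
noise. `train_pattern_model()` is principal-components regression with
5-fold cross-validation: within each training fold, patterns are centered,
projected onto components retaining at least 90% of the variance
(a documented default; the original analysis does not state its rule), and
the target is regressed on the scores; held-out trials are predicted by
the fold's model, so no trial's own target ever touches its prediction — a
leakage property the tests check by construction. The reported weight map
is the all-data refit after CV evaluation.

`fit_neural_utility()` substitutes the cross-validated predictions
$\hat\omega$ and $\hat E''$ into the reciprocity utility and re-estimates
$(\theta, \phi)$ by the same multi-start SSE procedure.
`phi_permutation_test()` asks whether the fitted $\phi$ carries
participant-specific information by re-predicting every participant with
permuted $\phi$ values; the p-value is the fraction of permuted mean
prediction correlations at or above the observed one.
`relative_pattern_similarity()` is the alignment statistic
$\mathrm{corr}(\vec w_{obl}, \vec w_{rec}) -
\mathrm{corr}(\vec w_{com}, \vec w_{rec})$, invariant to positive
rescaling of any map.

The default `snr = 0.11` is calibrated so that the cross-validated
prediction accuracy of both appraisal patterns falls in the ~0.1–0.2 range
reported for real outcome-period activity; this calibration targets the
CV accuracy only. A known limitation follows from the generator's
unstructured noise: at that accuracy regime, isotropic-noise patterns
carry substantially less appraisal information than real imaging data of
equal CV accuracy (where noise is spatially structured and condition-level
signal dominates), so across-participant recovery of $\phi$ from patterns
alone is weaker here than the empirical analogue, while the permutation
test and the pattern-similarity association remain clearly positive. The
acceptance suite reports this honestly rather than tuning the generator
to the statistic.

## Problem sizes and runtime

The shipped tests and the acceptance script use cohorts of 40–50
participants, 48–56 trials each, 200-feature patterns, 20 optimization
restarts, and 2000–5000 permutations — sizes chosen so a full run
completes in a few minutes on a single core while keeping every
statistical check comfortably powered. All randomness flows through
explicit integer seeds; repeated runs with the same seed are bit-identical.

## Session info

```{r}
sessionInfo()
```
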
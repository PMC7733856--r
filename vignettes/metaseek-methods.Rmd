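---
title: "Modelling uncertainty-guided information seeking with metaseek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling uncertainty-guided information seeking with metaseek}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaseek)
```

## The scientific problem

In a costed perceptual information-seeking task, an observer judges which of
two flickering boxes contains more dots, rates confidence on a signed
six-point scale, and then decides whether to pay (5 or 20 points, fixed per
block) to view a stronger version of the stimulus before an incentivized
final decision (100 points if correct, 0 otherwise). Well-calibrated
observers should buy information precisely when they are uncertain. The
question metaseek is built around is an individual-differences one: do
people with more dogmatic worldviews make less use of their own uncertainty
when deciding whether to seek more evidence?

Because the package works entirely from synthetic cohorts, every analysis
can be validated by parameter recovery: we simulate data with known
parameters, run the estimation machinery, and check that the truth comes
back.

## The seek model

Each trial's decision to seek information is modelled as a Bernoulli draw
with

$$P(\text{seek}) = \mathrm{logit}^{-1}(\beta_0 + \beta_1\,\text{Confidence} + \beta_2\,\text{Cost}),$$

where Confidence is the pooled z-score of the 3-level confidence magnitude
and Cost is a high-cost indicator (1 for the 20-point blocks). $\beta_0$
captures a general disposition to seek, $\beta_1$ the coupling of seeking
to confidence (negative in typical observers: less seeking when sure), and
$\beta_2$ cost sensitivity (negative: less seeking when expensive).

Confidence is z-scored with the population (1/n) standard deviation, so
that equally frequent levels \{1, 2, 3\} map exactly to
$\pm\sqrt{3/2} \approx \pm 1.2247$ and 0; the simulator uses the same
canonical encoding $(\ell - 2)/\sqrt{2/3}$ inside its generative policy, so
generative and fitted scales agree on balanced data. Two cost levels admit
only a binary contrast, hence the indicator coding.

## Hierarchical estimation with an embedded covariate

Per-subject maximum likelihood (`fit_subject_mle()`) is noisy at 100 trials
per subject, so the primary estimator is hierarchical
(`fit_hierarchical()`): subject coefficients are drawn from group priors
whose means shift linearly with the subject's dogmatism z-score,

$$\beta_{k,i} \sim \mathcal{N}(\mu_{B_k} + \rho_k \cdot \text{Dogmatism}_i,\ \sigma_{B_k}), \qquad k = 0, 1, 2.$$

Embedding the covariate in the prior, rather than correlating point
estimates with it afterwards, propagates per-subject estimation uncertainty
into the association parameters $\rho_k$; a $\rho_k$ whose central 95%
credible interval excludes zero (closed at the endpoints) is reported as a
significant association (`summarize_embedding()`).

Choices that were genuinely open and how we resolved them:

* **Hyperpriors.** $\mathcal{N}(0, 5)$ on each $\mu_{B_k}$ and $\rho_k$,
  Half-Normal$(0, 2.5)$ on each $\sigma_{B_k}$ — weakly informative on the
  logit scale, wide relative to any plausible seek policy.
* **Sampler.** JAGS, 4 chains of 1000 kept draws after 500 adaptation and
  1000 warmup iterations (all configurable). Convergence is monitored with
  a rank-normalized split R-hat (threshold 1.01, a warning, not an error)
  and effective sample sizes.
* **Likelihood aggregation.** Trials are collapsed to binomial counts per
  (subject, confidence level, cost) cell before sampling. The likelihood is
  identical to the trial-level Bernoulli product; the node count drops by
  ~95% and a 568-subject fit completes in about a minute on one CPU.
* **Scaling of the covariate.** Dogmatism scores are z-scored before
  embedding, so $\rho_k$ is the shift per SD of dogmatism.
* **Inclusion.** Only subjects who sought information on at least 5% and at
  most 95% of trials enter the fit (`filter_inclusion()`, closed bounds);
  outside those bounds the policy parameters are barely identified.

One property worth knowing: per-subject posterior-mean intercepts are not
related to the per-subject ML intercepts by one-dimensional shrinkage,
because the ML intercept is estimated jointly with free slopes and the
uncentered cost indicator couples the intercept and the cost effect.
Shrinkage toward the embedded prior mean holds in aggregate (and partial
pooling roughly halves the intercept error SD against the truth), but not
subject-by-subject; the test suite asserts the aggregate form.

## The generative simulator

`simulate_cohort()` produces complete synthetic studies. Its defaults are
the task's design constants: 4 blocks of 25 trials; costs 5/20 assigned to
blocks 1,3/2,4 (counterbalancing is a config option); payoff
100/0; a 120-trial calibration phase; signed six-point confidence codes
("sure left" = 1 ... "sure right" = 6).

* **Psychometric mapping.** The decision variable is
  $x \sim \mathcal{N}(d \cdot \text{side}, 1)$ with
  $d = s \cdot \log(1 + \Delta/313)/\sqrt{2}$: Weber-like log scaling on
  the 313-dot baseline, and the $\sqrt{2}$ of a two-interval differencing
  observer, so initial accuracy is $\Phi(d)$ (plus a lapse of at most 5%,
  default up to 2%, responding at random). One internally consistent form
  is used for calibration, trial simulation and probe accuracy alike.
* **Staircase.** Two-down-one-up on the log dot difference with trial-wise
  feedback, converging where accuracy is $\sqrt{1/2} \approx 70.7\%$ —
  matching the task's ~71% target. The step halves after the first three
  reversals and the returned level is the mean of all later reversal
  points. A single 120-trial staircase carries an irreducible
  accuracy-scale spread of roughly 4–5 percentage points (120 Bernoulli
  trials cannot pin a 71% threshold more tightly than
  $\sqrt{0.71 \cdot 0.29/120} \approx 4$ points, whatever the estimator),
  so calibration-accuracy checks average over replicate calibrations; the
  cohort does this naturally across subjects.
* **Post-decision evidence.** When the observer pays, a second draw at 3×
  the calibrated log-strength (config: `postdecision_multiplier`) is added
  to the running evidence; the stronger look alone supports roughly 95%
  accuracy at default sensitivity. Without seeking, the final choice
  deterministically repeats the initial one — unprompted changes of mind
  are not modelled.
* **Factor scores.** Orientation, dogmatism and belief superiority are
  generated with the observed population structure: dogmatism rises
  linearly and quadratically with orientation; superiority falls linearly
  and rises quadratically with orientation and rises with dogmatism; all
  three are standardized. Default coefficients
  (`default_factor_structure()`) sit in the range reported for large
  online samples (linear ~0.2, quadratic ~0.35 for dogmatism), with noise
  SDs chosen so the quadratic structure is visible but far from
  deterministic.
* **Population seek policy.** Defaults
  $\mu_B = (0, -1, -0.8)$, $\sigma_B = (1, 0.5, 0.5)$: negative confidence
  and cost slopes of moderate size on the logit scale and wide individual
  variation, giving cohorts whose seek rates spread over most of the 5–95%
  inclusion range. Embedding slopes default to zero; recovery studies
  switch them on explicitly.
* **Observers.** Sensitivity is log-normal (median 9 per unit
  log-dot-difference, so calibrated differences land in the tens of dots);
  confidence criteria (0.6, 1.3 on |evidence|) get per-subject log-normal
  jitter; demographics match a broad online adult sample.

### What the synthetic data do and do not emulate

The generator reproduces the statistical structure the analyses rely on:
calibrated ~71% initial accuracy, confidence levels informative about
accuracy, cost- and confidence-sensitive seeking, improved final accuracy
after seeking, the points ledger, and dogmatism-shifted policy parameters.
It does not emulate sequential effects (learning, fatigue, block order),
reaction times, response biases, lapses of the confidence report itself, or
any motivated-reasoning component — in real data those could all attenuate
or confound the associations that recover cleanly here. Passing recovery
tests therefore validates the estimation machinery, not the substantive
claim in any particular real dataset.

## Group-level analyses

`standardized_regression()` z-scores continuous variables (standardized
betas), dummy-codes gender with a female reference, and reports the focal
predictor's $\Delta R^2$ against the same model without it. Replication
analyses use a one-tailed option whose hypothesized direction must be given
explicitly. "Objective stimulus strength" enters as the log of the
calibrated dot difference. `polynomial_factor_fit()` compares linear,
quadratic and combined fits by BIC with ties broken toward fewer
parameters. `pool_samples()` concatenates studies for the internal
meta-analysis, tags rows, and re-standardizes factor scores on the pooled
sample; behavioural aggregates stay on their natural scale because the
regression function standardizes at fit time.

`quasi_bayes_mediation()` tests dogmatism → seek rate → final accuracy with
the same covariates on all paths: OLS mediator and outcome models, 1000+
draws from the multivariate-normal approximation to the coefficient
sampling distributions, ACME $= a \cdot b$, ADE $= c'$ and percentile
intervals per draw. For these linear models total $=$ ACME $+$ ADE holds
exactly per draw. Accuracy is used as a linear proportion (the subject-level
regressions do the same); logistic outcome models are out of scope.

## Numerical choices and degenerate inputs

Logistic predictors are clipped at ±30, so probabilities stay strictly
inside (0, 1). Zero-variance confidence encodes as 0 with a warning rather
than failing. All-0/all-1 seek outcomes yield flagged boundary estimates
(intercept ±5) instead of divergent fits; complete separation is flagged
`separable`. Observers too weak to reach 60% accuracy at the maximum
312-dot difference raise a calibration failure naming the subject. Every
stochastic function takes an explicit integer seed and restores the global
RNG state; pipelines re-run to identical checksums.

## Problem sizes used in validation

The package's own validation runs at the scale the analyses are meant for:
staircase convergence is checked on 1000-trial runs and on the average of
ten 120-trial calibrations; cohort accuracy on 50 subjects × 100 trials;
full hierarchical recovery on 568 subjects × 100 trials with
$\rho = (-0.24, 0.15, 0)$ (signs and 2-posterior-SD recovery, with the
5–95% filter applied first); null calibration on twenty 200-subject
replicates with shorter chains (2 × 750 kept draws — a Monte-Carlo budget
chosen for the replicate study); mediation interval coverage on one hundred
n = 500 replicates.

## Known limitations

JAGS's generic samplers are slower than a hand-tuned HMC implementation;
very large cohorts (thousands of subjects) would warrant a non-centered
parameterization. The mediation module assumes sequential ignorability and
offers no sensitivity analysis. The factor-score generator emits scores
directly rather than item-level questionnaire responses, so factor-analytic
steps (extraction, rotation) are outside the package's scope.
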
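# metaseek

Simulation and hierarchical modelling of uncertainty-guided information
seeking in costed perceptual decision tasks.

## What this is for

In the task this package models, a participant judges which of two
flickering boxes holds more dots, rates confidence on a signed six-point
scale, and may then pay (5 or 20 points, fixed per block) to see a
stronger version of the stimulus before a final, incentivized decision
(100 points if correct). Observers who regulate behaviour by their own
uncertainty should buy information exactly when confidence is low. The
scientific question the package is built around is whether
individual differences — in particular a questionnaire-derived *dogmatism*
factor — are associated with how much, and how adaptively, people seek
information.

Because raw participant data for such studies are rarely deposited, the
package ships a full generative simulator and validates every analysis by
parameter recovery on synthetic cohorts. It is aimed at computational
cognitive modellers who want a tested reference implementation of:

* a signal-detection trial simulator with confidence criteria, lapses,
  two-down-one-up staircase calibration (converging at √½ ≈ 70.7%
  accuracy) and costed post-decision evidence;
* the trial-by-trial logistic **seek model**
  `P(seek) = logit⁻¹(β₀ + β₁·Confidence + β₂·Cost)`;
* hierarchical Bayesian estimation with the covariate **embedded in the
  group priors**, `β_k,i ~ N(µ_Bk + ρ_k·Dogmatismᵢ, σ_Bk)`, so that a 95%
  credible interval on ρ_k that excludes zero indicates an association
  between dogmatism and that policy parameter;
* subject-level standardized regressions with ΔR², BIC-selected polynomial
  factor relationships, sample pooling for internal meta-analysis, and
  quasi-Bayesian Monte Carlo mediation (ACME / ADE / total effect).

## Worked example

Simulate a 120-subject cohort whose population embeds a negative dogmatism
effect on baseline seeking (ρ₀ = −0.4) and a positive effect on the
confidence slope (ρ₁ = +0.3), then recover them:

```r
library(metaseek)

pop <- population_params(mu_B = c(0, -1, -0.8), sigma_B = c(1, 0.5, 0.5),
                         rho = c(-0.4, 0.3, 0))
cohort <- simulate_cohort(cohort_config(n_subjects = 120, population = pop,
                                        seed = 2026))
mean(cohort$trials$initial_correct)   # 0.697 — the staircase's ~71% target
mean(cohort$trials$sought)            # 0.469

include <- filter_inclusion(cohort$subjects$seek_rate)   # 5%-95% rule
kept <- cohort$subjects$subject_id[include]
design <- encode_predictors(subset(cohort$trials, subject_id %in% kept))
dogmatism <- setNames(cohort$subjects$dogmatism,
                      cohort$subjects$subject_id)[kept]
fit <- fit_hierarchical(design, dogmatism, n_chains = 2, n_warmup = 500,
                        n_draws = 500, seed = 9)
summarize_embedding(fit)
#> # A tibble: 3 × 5
#>   parameter    mean   q2.5   q97.5 excludes_zero
#> 1 rho0      -0.276  -0.484 -0.0852 TRUE
#> 2 rho1       0.396   0.291  0.505  TRUE
#> 3 rho2      -0.0794 -0.225  0.0570 FALSE
```

Both embedded effects are recovered with intervals excluding zero, and the
null cost-slope effect is not flagged. (Short demonstration chains like
these can emit a non-fatal convergence warning; production fits default to
4 chains × 1000 draws.)

The model-agnostic analyses run on the subject table:

```r
standardized_regression(cohort$subjects, "dogmatism", "seek_rate",
                        c("age", "gender", "education",
                          "initial_accuracy", "mean_confidence"))
#> <regression_result> dogmatism ~ seek_rate (+ 6 covariate terms), n = 120
#>   standardized beta = -0.298 (SE 0.088), two-tailed p = 0.000989
#>   R2 = 0.1677 vs 0.0827 without focal; delta R2 = 0.0850

quasi_bayes_mediation(cohort$subjects, "dogmatism", "seek_rate",
                      "final_accuracy", c("age", "education",
                      "initial_accuracy"), n_draws = 2000, seed = 10)
#> <mediation_result> dogmatism -> seek_rate -> final_accuracy, n = 120, 2000 draws
#>   ACME   -0.1809  [-0.2940, -0.0744]
#>   ADE    -0.0792  [-0.1662, 0.0107]
#>   total  -0.2601  [-0.3964, -0.1213]
#>   proportion mediated (median): 0.691
```

More dogmatic simulated subjects seek less (standardized β = −0.30), and
their lower final accuracy is largely mediated by that reduced seeking —
the qualitative pattern the embedded population parameters encode.

`run_pipeline()` chains all stages (simulate → fit → analyze → mediate →
report) from a YAML/list config into a directory of CSV/JSON artifacts, a
markdown report and a provenance log, reproducible checksum-for-checksum
from the seed.

## Package layout

| area | functions |
|---|---|
| simulator | `observer_params`, `population_params`, `cohort_config`, `generate_factor_scores`, `sample_subject_params`, `calibrate_staircase`, `simulate_trials`, `simulate_cohort` |
| seek model | `encode_predictors`, `seek_probability`, `subject_nll`, `fit_subject_mle`, `filter_inclusion`, `fit_hierarchical`, `summarize_embedding`, `predict_group_curves` |
| group analyses | `standardized_regression`, `polynomial_factor_fit`, `pool_samples`, `quasi_bayes_mediation` |
| io / pipeline | `read_trials`, `write_trials`, `read_subjects`, `write_subjects`, `aggregate_subjects`, `run_pipeline` |

The methods vignette (`vignettes/metaseek-methods.Rmd`) documents the
generative model, the hierarchical estimator, every tunable default and
the validation problem sizes.
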
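# One moderately sized fit is shared across the recovery, shrinkage and
# diagnostics expectations to keep the suite fast.
fit_cache <- local({
  pop <- population_params(mu_B = c(0, -1, -0.8), sigma_B = c(0.8, 0.4, 0.4),
                           rho = c(-0.5, 0.3, 0))
  cohort <- make_policy_cohort(60, pop, n_trials = 100, seed = 61)
  fit <- suppressWarnings(
    fit_hierarchical(cohort$design, cohort$dogmatism,
                     n_chains = 2, n_warmup = 500, n_draws = 500,
                     seed = 62))
  list(pop = pop, cohort = cohort, fit = fit)
})

test_that("hierarchical fit recovers population means and embedding signs", {
  s <- fit_cache$fit$summary
  grab <- function(p) s[s$parameter == p, ]
  for (k in 1:3) {
    mu_k <- grab(paste0("mu_B", k - 1))
    expect_lt(abs(mu_k$mean - fit_cache$pop$mu_B[k]), 2.5 * mu_k$sd + 0.1)
  }
  expect_lt(grab("rho0")$mean, 0)
  expect_gt(grab("rho1")$mean, 0)
  # sigma posteriors live strictly above zero
  sig <- s[s$parameter %in% paste0("sigma_B", 0:2), ]
  expect_true(all(sig$q2.5 > 0))
  expect_true(all(fit_cache$fit$group_draws[, paste0("sigma_B", 0:2)] > 0))
  # interval ordering and diagnostics reported for every parameter
  expect_true(all(s$q2.5 <= s$mean & s$mean <= s$q97.5))
  expect_true(all(is.finite(s$rhat)))
  expect_true(all(s$ess > 0))
})

test_that("hierarchical posterior means shrink toward the embedded prior", {
  # the per-subject ML intercept is estimated jointly with free slopes, so
  # 1-D shrinkage need not hold subject by subject; it must hold in
  # aggregate, and partial pooling must reduce error against the truth
  fit <- fit_cache$fit
  s <- fit$summary
  mu0 <- s$mean[s$parameter == "mu_B0"]
  rho0 <- s$mean[s$parameter == "rho0"]
  design <- fit_cache$cohort$design
  dog <- fit$dogmatism
  ids <- fit$subject_ids
  dist_mle <- dist_post <- err_mle <- err_post <- numeric(0)
  for (i in seq_along(ids)) {
    mle <- fit_subject_mle(design[design$subject_id == ids[i], ])
    if (mle$fit_flag != "ok") next
    prior_mean <- mu0 + rho0 * dog[ids[i]]
    dist_mle <- c(dist_mle, abs(mle$betas["b0"] - prior_mean))
    dist_post <- c(dist_post, abs(fit$subject_means[i, "b0"] - prior_mean))
    err_mle <- c(err_mle, mle$betas["b0"] - fit_cache$cohort$betas[i, "b0"])
    err_post <- c(err_post,
                  fit$subject_means[i, "b0"] - fit_cache$cohort$betas[i, "b0"])
  }
  expect_lt(mean(dist_post), mean(dist_mle))
  expect_lt(sd(err_post), sd(err_mle))
  expect_gt(mean(dist_post <= dist_mle), 0.5)
})

test_that("with tiny population spread the group means approach the pooled MLE", {
  pop <- population_params(mu_B = c(0.3, -0.9, -0.6),
                           sigma_B = rep(0.05, 3), rho = c(0, 0, 0))
  cohort <- make_policy_cohort(30, pop, n_trials = 200, seed = 71)
  fit <- suppressWarnings(
    fit_hierarchical(cohort$design, cohort$dogmatism,
                     n_chains = 2, n_warmup = 500, n_draws = 500,
                     seed = 72))
  pooled <- suppressWarnings(
    glm(sought ~ confidence_encoded + cost_encoded,
        family = binomial(), data = cohort$design))
  mu_hat <- fit$summary$mean[match(paste0("mu_B", 0:2), fit$summary$parameter)]
  expect_true(all(abs(mu_hat - unname(coef(pooled))) < 0.1))
})

test_that("degenerate inputs are rejected", {
  pop <- population_params()
  cohort <- make_policy_cohort(25, pop, n_trials = 30, seed = 81)
  expect_error(
    fit_hierarchical(cohort$design,
                     setNames(rep(0, 25), names(cohort$dogmatism))),
    class = "metaseek_embedding_unidentifiable")
  small <- cohort$design[cohort$design$subject_id %in%
                           names(cohort$dogmatism)[1:10], ]
  expect_error(fit_hierarchical(small, cohort$dogmatism[1:10]),
               class = "metaseek_invalid_argument")
  expect_error(fit_hierarchical(cohort$design, cohort$dogmatism[1:5]),
               class = "metaseek_invalid_argument")
})

test_that("embedding significance uses closed 95% intervals", {
  fake <- function(lo, hi) {
    structure(list(summary = tibble::tibble(
      parameter = c("rho0", "rho1", "rho2"),
      mean = (lo + hi) / 2, sd = 0.1, q2.5 = lo, q97.5 = hi,
      rhat = 1, ess = 100)), class = "seek_posterior")
  }
  expect_identical(
    summarize_embedding(fake(c(-0.40, -0.06, 0), c(-0.07, 0.07, 0.27)))$excludes_zero,
    c(TRUE, FALSE, FALSE))
})
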
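test_that("every generated trial satisfies the points identity and code mapping", {
  obs <- observer_params("s1", sensitivity = 9, betas = c(0.3, -1, -0.6))
  tr <- simulate_trials(obs, 25, cost_points = rep(c(5L, 20L), 200), seed = 4)
  expect_identical(tr$points,
                   as.integer(100L * tr$final_correct -
                                tr$cost_points * tr$sought))
  # six-point code: "sure left" = 1 ... "sure right" = 6
  left <- tr$initial_choice == "left"
  expect_identical(tr$initial_conf_code6[left],
                   4L - tr$initial_conf_level[left])
  expect_identical(tr$initial_conf_code6[!left],
                   3L + tr$initial_conf_level[!left])
  # unsought trials repeat the initial choice and confidence
  stay <- !tr$sought
  expect_identical(tr$final_choice[stay], tr$initial_choice[stay])
  expect_identical(tr$final_conf_level[stay], tr$initial_conf_level[stay])
})

test_that("a near-perfect observer is almost always correct and certain", {
  obs <- observer_params("s2", sensitivity = 5000, lapse_rate = 0)
  tr <- simulate_trials(obs, 50, cost_points = 5L, n_trials = 500, seed = 6)
  expect_true(all(tr$initial_correct))
  expect_true(all(tr$initial_conf_level == 3L))
})

test_that("logistic saturation makes seeking vanish at high confidence", {
  p <- seek_probability(c(0, -50, 0), (3 - 2) / sqrt(2 / 3), 0)
  expect_lt(p, 1e-6)
  obs <- observer_params("s3", sensitivity = 5000, lapse_rate = 0,
                         betas = c(0, -50, 0))
  tr <- simulate_trials(obs, 50, cost_points = 5L, n_trials = 300, seed = 9)
  expect_identical(sum(tr$sought), 0L)
})

test_that("negative cost sensitivity lowers seeking at the high cost", {
  obs <- observer_params("s4", sensitivity = 9, betas = c(0, -1, -0.8))
  lo <- simulate_trials(obs, 25, cost_points = 5L, n_trials = 10000, seed = 12)
  hi <- simulate_trials(obs, 25, cost_points = 20L, n_trials = 10000, seed = 13)
  expect_lt(mean(hi$sought), mean(lo$sought))
})

test_that("seek rate decreases with confidence level when beta1 < 0", {
  obs <- observer_params("s5", sensitivity = 9, betas = c(0.5, -1.2, -0.5))
  tr <- simulate_trials(obs, 25, cost_points = rep(c(5L, 20L), 5000), seed = 14)
  rates <- tapply(tr$sought, tr$initial_conf_level, mean)
  expect_true(all(diff(rates) < 0))
})

test_that("simulated cohorts hit the calibration target and behave adaptively", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 30, seed = 5))
  acc <- mean(cohort$trials$initial_correct)
  expect_gt(acc, 0.66)
  expect_lt(acc, 0.76)
  # information is sought more often after initial errors
  tr <- cohort$trials
  expect_gt(mean(tr$sought[!tr$initial_correct]),
            mean(tr$sought[tr$initial_correct]))
  # cost is constant within a block
  by_block <- unique(tr[c("subject_id", "block", "cost_points")])
  expect_identical(nrow(by_block), 30L * 4L)
})

test_that("forced seeking with strong post-decision evidence raises accuracy", {
  pop <- population_params(mu_B = c(20, 0, 0), sigma_B = rep(1e-6, 3))
  cfg <- cohort_config(n_subjects = 15, population = pop,
                       postdecision_multiplier = 3, seed = 7)
  cohort <- simulate_cohort(cfg)
  expect_true(all(cohort$trials$sought))
  expect_gt(mean(cohort$trials$final_correct),
            mean(cohort$trials$initial_correct))
})

test_that("cohort generation is byte-identical given the seed", {
  cfg <- cohort_config(n_subjects = 8, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$subjects, b$subjects)
})

test_that("trial simulation validates its arguments", {
  obs <- observer_params("s6", sensitivity = 9)
  expect_error(simulate_trials(obs, 25, cost_points = 7L, n_trials = 10),
               class = "metaseek_invalid_argument")
  expect_error(simulate_trials(obs, 0, cost_points = 5L, n_trials = 10),
               class = "metaseek_invalid_argument")
  expect_error(cohort_config(cost_schedule = c(5L, 5L, 5L, 5L)),
               class = "metaseek_invalid_argument")
})
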
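test_that("predictor encoding matches the closed-form z-scores", {
  trials <- tibble::tibble(subject_id = "a", sought = c(TRUE, FALSE, TRUE),
                           initial_conf_level = c(1L, 2L, 3L),
                           cost_points = c(5L, 20L, 5L))
  enc <- encode_predictors(trials)
  expect_equal(enc$confidence_encoded, c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  expect_identical(enc$cost_encoded, c(0L, 1L, 0L))
  expect_identical(enc$sought, c(1L, 0L, 1L))

  # degenerate confidence encodes as zero with a warning
  flat <- trials; flat$initial_conf_level <- c(2L, 2L, 2L)
  expect_warning(enc0 <- encode_predictors(flat), "zero variance")
  expect_identical(enc0$confidence_encoded, c(0, 0, 0))

  bad <- trials; bad$cost_points[2] <- 7L
  err <- expect_error(encode_predictors(bad), class = "metaseek_schema_error")
  expect_match(conditionMessage(err), "row 2")
  bad2 <- trials; bad2$initial_conf_level[3] <- 4L
  expect_error(encode_predictors(bad2), class = "metaseek_schema_error")
})

test_that("seek_probability matches a brute-force logistic to 1e-12", {
  expect_equal(seek_probability(c(0, 0, 0), 2, 1), 0.5)
  expect_equal(seek_probability(c(1, -2, 0), 0.5, 1), 0.5)
  withr::with_seed(42, {
    for (i in 1:200) {
      b <- runif(3, -3, 3); conf <- runif(1, -2, 2); cost <- rbinom(1, 1, 0.5)
      expect_equal(seek_probability(b, conf, cost),
                   brute_logistic(b, conf, cost), tolerance = 1e-12)
    }
  })
  # always strictly inside (0, 1), even at absurd coefficients
  expect_gt(seek_probability(c(-1000, 0, 0), 0, 0), 0)
  expect_lt(seek_probability(c(1000, 0, 0), 0, 0), 1)
})

test_that("subject_nll equals the brute-force Bernoulli sum", {
  one <- tibble::tibble(sought = 1L, confidence_encoded = 0, cost_encoded = 0L)
  expect_equal(subject_nll(c(0, 0, 0), one), log(2), tolerance = 1e-12)

  sat <- tibble::tibble(sought = rep(1L, 20), confidence_encoded = 0,
                        cost_encoded = 0L)
  expect_lt(subject_nll(c(1e6, 0, 0), sat), 1e-8)

  d <- make_design(c(0.4, -0.9, -0.5), n_trials = 50, seed = 15)
  b <- c(0.2, -1.1, -0.3)
  expect_equal(subject_nll(b, d), brute_nll(b, d), tolerance = 1e-10)
  expect_error(subject_nll(c(0, 0, 0), d[0, ]),
               class = "metaseek_invalid_argument")
})

test_that("per-subject MLE recovers generating betas at large n", {
  truth <- c(0.5, -1.0, -0.5)
  d <- make_design(truth, n_trials = 10000, seed = 33)
  fit <- fit_subject_mle(d)
  expect_identical(fit$fit_flag, "ok")
  expect_true(all(abs(fit$betas - truth) < 0.1))
  # the fitted NLL is no worse than the truth's
  expect_lte(subject_nll(fit$betas, d), subject_nll(truth, d))
})

test_that("degenerate seek data are flagged rather than fitted", {
  sep <- tibble::tibble(subject_id = "s",
                        sought = as.integer(enc3(rep(1:3, each = 10)) < 0),
                        confidence_encoded = enc3(rep(1:3, each = 10)),
                        cost_encoded = rep_len(c(0L, 1L), 30))
  expect_identical(fit_subject_mle(sep)$fit_flag, "separable")

  all1 <- tibble::tibble(subject_id = "s", sought = rep(1L, 20),
                         confidence_encoded = rnorm(20),
                         cost_encoded = rep_len(c(0L, 1L), 20))
  b <- fit_subject_mle(all1)
  expect_identical(b$fit_flag, "boundary")
  expect_equal(unname(b$betas), c(5, 0, 0))
  expect_error(fit_subject_mle(all1[1:5, ]),
               class = "metaseek_invalid_argument")
})

test_that("the 5%-95% inclusion filter uses closed bounds", {
  expect_identical(filter_inclusion(c(0.04, 0.05, 0.5, 0.95, 0.96)),
                   c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_error(filter_inclusion(c(0.5, 1.2)),
               class = "metaseek_invalid_argument")
})
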
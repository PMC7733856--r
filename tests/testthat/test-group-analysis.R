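make_subject_df <- function(n, beta_focal, seed) {
  withr::with_seed(seed, {
    seek <- rnorm(n)
    age <- rnorm(n, 37, 11)
    edu <- rnorm(n)
    out <- beta_focal * scale(seek)[, 1] + 0.2 * scale(age)[, 1] +
      rnorm(n, sd = sqrt(max(0.1, 1 - beta_focal^2 - 0.04)))
    data.frame(outcome = out, seek_rate = seek, age = age, education = edu,
               gender = sample(c("female", "male"), n, replace = TRUE))
  })
}

test_that("null focal effects are recovered as null", {
  df <- make_subject_df(5000, 0, seed = 101)
  res <- standardized_regression(df, "outcome", "seek_rate",
                                 c("age", "education", "gender"))
  expect_lt(abs(res$focal_estimate), 3 * res$focal_se)
  expect_gte(res$delta_r2, 0)
})

test_that("a -0.15 standardized focal effect is recovered with covariates", {
  df <- make_subject_df(5000, -0.15, seed = 102)
  res <- standardized_regression(df, "outcome", "seek_rate",
                                 c("age", "education", "gender"))
  expect_lt(abs(res$focal_estimate - (-0.15)), 3 * res$focal_se)
  expect_gt(res$r2_full, res$r2_reduced)
})

test_that("standardized coefficients are invariant to affine rescaling", {
  df <- make_subject_df(800, -0.2, seed = 103)
  res1 <- standardized_regression(df, "outcome", "seek_rate", c("age", "gender"))
  df2 <- df
  df2$seek_rate <- 100 * df2$seek_rate - 7
  df2$age <- df2$age / 365
  res2 <- standardized_regression(df2, "outcome", "seek_rate", c("age", "gender"))
  expect_equal(res1$focal_estimate, res2$focal_estimate, tolerance = 1e-10)
  expect_equal(res1$delta_r2, res2$delta_r2, tolerance = 1e-10)
})

test_that("one-tailed p-values halve in the hypothesized direction", {
  df <- make_subject_df(500, -0.2, seed = 104)
  two <- standardized_regression(df, "outcome", "seek_rate", "age")
  one <- standardized_regression(df, "outcome", "seek_rate", "age",
                                 tails = "one", direction = -1)
  expect_equal(one$focal_p, two$focal_p / 2, tolerance = 1e-10)
  wrong <- standardized_regression(df, "outcome", "seek_rate", "age",
                                   tails = "one", direction = 1)
  expect_gt(wrong$focal_p, 0.5)
})

test_that("collinear designs fail loudly", {
  df <- make_subject_df(200, -0.2, seed = 105)
  df$age_copy <- df$age
  err <- expect_error(
    standardized_regression(df, "outcome", "seek_rate",
                            c("age", "age_copy")),
    class = "metaseek_collinearity_error")
  expect_match(conditionMessage(err), "age_copy")
})

test_that("BIC model selection identifies the generating polynomial", {
  withr::with_seed(111, {
    x <- as.numeric(scale(rnorm(2000)))
    lin <- polynomial_factor_fit(x, x + rnorm(2000, sd = 0.3))
    quad <- polynomial_factor_fit(x, x^2 - 1 + rnorm(2000, sd = 0.3))
    noise <- polynomial_factor_fit(x, rnorm(2000))
  })
  expect_identical(lin$selected, "linear")
  expect_true(quad$selected %in% c("quadratic", "combined"))
  expect_gt(quad$coefficients$combined[["I(x^2)"]], 0)
  # parsimony under the null: the extra-parameter model never wins
  expect_true(noise$selected != "combined")
  expect_lt(noise$bic[["linear"]], noise$bic[["combined"]])
  expect_error(polynomial_factor_fit(rep(1, 50), rnorm(50)),
               class = "metaseek_invalid_argument")
})

test_that("BIC selection sharpens with sample size", {
  pick <- function(n, seed) {
    withr::with_seed(seed, {
      x <- as.numeric(scale(rnorm(n)))
      y <- 0.15 * x + 0.15 * (x^2 - 1) + rnorm(n, sd = 1)
    })
    polynomial_factor_fit(x, y)$selected
  }
  big <- vapply(1:5, function(s) pick(5000, 200 + s), character(1))
  expect_true(all(big == "combined"))
})

test_that("pooling is duplication-invariant and tightens standard errors", {
  fs <- generate_factor_scores(400, seed = 121)
  fs$seek_rate <- withr::with_seed(122,
                                   -0.2 * fs$dogmatism + rnorm(400, sd = 0.9))
  fs$study <- "study1"
  pooled <- pool_samples(fs, fs, study_labels = c("study1", "study2"))
  expect_identical(nrow(pooled), 800L)
  r1 <- standardized_regression(fs, "dogmatism", "seek_rate", character())
  r2 <- standardized_regression(pooled, "dogmatism", "seek_rate", character())
  expect_equal(r1$focal_estimate, r2$focal_estimate, tolerance = 1e-10)

  # two independent studies with the same effect: pooled SE shrinks
  fs2 <- generate_factor_scores(400, seed = 123)
  fs2$seek_rate <- withr::with_seed(124,
                                    -0.2 * fs2$dogmatism + rnorm(400, sd = 0.9))
  fs2$study <- "study2"
  pooled2 <- pool_samples(fs, fs2)
  r3 <- standardized_regression(pooled2, "dogmatism", "seek_rate", character())
  r4 <- standardized_regression(fs2, "dogmatism", "seek_rate", character())
  expect_lt(r3$focal_se, min(r1$focal_se, r4$focal_se))

  expect_error(pool_samples(), class = "metaseek_invalid_argument")
  fs3 <- fs2[setdiff(names(fs2), "seek_rate")]
  err <- expect_error(pool_samples(fs, fs3), class = "metaseek_schema_error")
  expect_match(conditionMessage(err), "seek_rate")
})
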
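#' Quasi-Bayesian Monte Carlo mediation analysis
#'
#' Tests whether the effect of a treatment variable (dogmatism) on an
#' outcome (final-decision accuracy) operates through a mediator
#' (information-seeking rate). Two OLS models are fitted — the mediator
#' model `M ~ X + C` and the outcome model `Y ~ X + M + C`, with the same
#' covariates `C` on all paths — and coefficient vectors are drawn from the
#' multivariate-normal approximation to their sampling distributions. Each
#' draw yields an average causal mediation effect `ACME = a * b`, an average
#' direct effect `ADE = c'` and their sum, the total effect; percentile
#' intervals over draws quantify uncertainty. Continuous variables are
#' z-scored before fitting, so effects are on the standardized scale.
#'
#' @param data Subject-level data frame.
#' @param treatment,mediator,outcome Column names.
#' @param covariates Character vector of covariate column names (entered
#'   into both models).
#' @param n_draws Number of Monte Carlo draws (>= 1000).
#' @param seed Integer seed.
#' @param conf_level Interval mass (default 0.95).
#' @param tails `"two"` for central percentile intervals (default) or
#'   `"one"` for a replication-style one-sided interval in the direction of
#'   the ACME point estimate.
#'
#' @return An object of class `mediation_result` with point estimates and
#'   intervals for ACME, ADE, total effect and proportion mediated, plus
#'   the per-draw effects.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(500))
#' d$m <- 0.5 * d$x + rnorm(500)
#' d$y <- 0.4 * d$m + rnorm(500)
#' quasi_bayes_mediation(d, "x", "m", "y", n_draws = 1000, seed = 2)
quasi_bayes_mediation <- function(data, treatment, mediator, outcome,
                                  covariates = character(),
                                  n_draws = 1000L, seed = 1L,
                                  conf_level = 0.95,
                                  tails = c("two", "one")) {
  tails <- match.arg(tails)
  n_draws <- assert_count(n_draws, "n_draws", min = 1000L)
  used <- c(treatment, mediator, outcome, covariates)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop_schema(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(data[used])
  if (any(!complete.cases(df))) stop_invalid("missing values in analysis columns")
  if (nrow(df) <= length(used) + 2L) stop_invalid("too few rows for the design")
  if (sd(df[[mediator]]) == 0) stop_invalid("mediator has zero variance")

  is_cont <- vapply(df, is.numeric, TRUE)
  df[is_cont] <- lapply(df[is_cont], zscore_sample)

  # canonical covariate order so results are invariant to how the caller
  # ordered the columns (the Monte Carlo draws depend on coefficient order)
  covariates <- sort(covariates)
  m_fit <- lm(stats::reformulate(c(treatment, covariates), response = mediator),
              data = df)
  y_fit <- lm(stats::reformulate(c(treatment, mediator, covariates),
                                 response = outcome), data = df)

  draws <- withr::with_seed(seed, {
    m_draw <- MASS::mvrnorm(n_draws, coef(m_fit), vcov(m_fit))
    y_draw <- MASS::mvrnorm(n_draws, coef(y_fit), vcov(y_fit))
    a <- m_draw[, treatment]
    b <- y_draw[, mediator]
    cprime <- y_draw[, treatment]
    tibble::tibble(draw = seq_len(n_draws),
                   acme = a * b, ade = cprime, total = a * b + cprime)
  })

  alpha <- 1 - conf_level
  ci <- function(x) {
    if (tails == "one") {
      est <- median(x)
      if (est >= 0) c(quantile(x, alpha, names = FALSE), Inf)
      else c(-Inf, quantile(x, 1 - alpha, names = FALSE))
    } else {
      quantile(x, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    }
  }
  point <- function(x) mean(x)
  prop_mediated <- median(draws$acme / draws$total)

  structure(list(
    acme = c(estimate = point(draws$acme), setNames(ci(draws$acme), c("lower", "upper"))),
    ade = c(estimate = point(draws$ade), setNames(ci(draws$ade), c("lower", "upper"))),
    total = c(estimate = point(draws$total), setNames(ci(draws$total), c("lower", "upper"))),
    prop_mediated = prop_mediated,
    draws = draws,
    n = nrow(df), n_draws = n_draws, seed = seed,
    conf_level = conf_level, tails = tails,
    treatment = treatment, mediator = mediator, outcome = outcome),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s, n = %d, %d draws\n",
              x$treatment, x$mediator, x$outcome, x$n, x$n_draws))
  fmt <- function(label, v) {
    cat(sprintf("  %-6s %7.4f  [%.4f, %.4f]\n", label,
                v["estimate"], v["lower"], v["upper"]))
  }
  fmt("ACME", x$acme); fmt("ADE", x$ade); fmt("total", x$total)
  cat(sprintf("  proportion mediated (median): %.3f\n", x$prop_mediated))
  invisible(x)
}
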
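#' Encode seek-model predictors from a trial table
#'
#' Builds the design table for the trial-by-trial logistic seek model:
#' confidence enters as the z-score of the 3-level initial confidence rating
#' pooled across all supplied trials (population-SD scaling, so equally
#' frequent levels map to -1.2247/0/+1.2247), and cost enters as a high-cost
#' indicator (1 when 20 points, 0 when 5). Row order is preserved.
#'
#' @param trials Trial table containing `subject_id`, `sought`,
#'   `initial_conf_level` in `{1,2,3}` and `cost_points` in `{5,20}`.
#' @return A tibble with columns `subject_id`, `sought` (0/1),
#'   `confidence_encoded`, `cost_encoded`.
#' @export
encode_predictors <- function(trials) {
  need <- c("subject_id", "sought", "initial_conf_level", "cost_points")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop_schema(paste0("trial table is missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  bad_conf <- which(!trials$initial_conf_level %in% 1:3)
  if (length(bad_conf)) {
    stop_schema(sprintf("unknown confidence level %s in row %d",
                        trials$initial_conf_level[bad_conf[1]], bad_conf[1]))
  }
  bad_cost <- which(!trials$cost_points %in% c(5L, 20L))
  if (length(bad_cost)) {
    stop_schema(sprintf("unknown cost value %s in row %d",
                        trials$cost_points[bad_cost[1]], bad_cost[1]))
  }
  conf <- as.numeric(trials$initial_conf_level)
  if (length(unique(conf)) == 1L) {
    warn("confidence has zero variance across trials; encoding it as 0")
    conf_enc <- rep(0, length(conf))
  } else {
    conf_enc <- zscore_pop(conf)
  }
  tibble::tibble(
    subject_id = as.character(trials$subject_id),
    sought = as.integer(trials$sought),
    confidence_encoded = conf_enc,
    cost_encoded = as.integer(trials$cost_points == 20L))
}

#' Logistic probability of seeking information
#'
#' The trial-by-trial seek policy:
#' `P(seek) = 1 / (1 + exp(-(b0 + b1 * confidence + b2 * cost)))`.
#' The linear predictor is clipped at +/-30 before the logistic transform so
#' the result stays strictly inside (0, 1).
#'
#' @param betas Numeric 3-vector `(b0, b1, b2)` (or a `SubjectBetas`-style
#'   list with a `betas` element).
#' @param confidence_encoded Encoded confidence (z-scored 3-level rating).
#' @param cost_encoded High-cost indicator (0/1).
#' @return Seek probability, vectorized over the predictors.
#' @export
#' @examples
#' seek_probability(c(0, 0, 0), 1, 1) # 0.5
seek_probability <- function(betas, confidence_encoded, cost_encoded) {
  if (is.list(betas)) betas <- betas$betas
  if (length(betas) != 3L || !all(is.finite(betas))) {
    stop_invalid("`betas` must be a finite numeric 3-vector")
  }
  eta <- betas[1] + betas[2] * confidence_encoded + betas[3] * cost_encoded
  eta <- pmin(30, pmax(-30, eta))
  1 / (1 + exp(-eta))
}

#' Bernoulli negative log-likelihood of the seek model
#'
#' @param betas Numeric 3-vector `(b0, b1, b2)`.
#' @param design Design table from [encode_predictors()] (columns `sought`,
#'   `confidence_encoded`, `cost_encoded`).
#' @return The negative sum of Bernoulli log-likelihoods (finite).
#' @export
subject_nll <- function(betas, design) {
  if (!nrow(design)) stop_invalid("`design` must contain at least one row")
  p <- seek_probability(betas, design$confidence_encoded, design$cost_encoded)
  -sum(ifelse(design$sought == 1L, log(p), log1p(-p)))
}

#' Per-subject maximum-likelihood fit of the seek model
#'
#' Fits the three seek-policy coefficients to one subject's trials by
#' logistic regression. Degenerate data are flagged rather than silently
#' returned: all-0 or all-1 seek outcomes give `fit_flag = "boundary"` with
#' the intercept clipped at +/-5 and zero slopes; perfectly predicted
#' outcomes (complete separation, diverging coefficients) give
#' `fit_flag = "separable"`. Hierarchical estimation
#' ([fit_hierarchical()]) is the recommended alternative when trial counts
#' are small: per-subject ML estimates are noisy at 100 trials.
#'
#' @param design Design rows for one subject (from [encode_predictors()]);
#'   at least 10 rows.
#' @return A list of class `subject_betas` with elements `betas` (named
#'   3-vector) and `fit_flag` (`"ok"`, `"separable"` or `"boundary"`).
#' @export
fit_subject_mle <- function(design) {
  if (nrow(design) < 10L) stop_invalid("need at least 10 rows to fit a subject")
  y <- design$sought
  if (all(y == y[1])) {
    return(structure(list(
      betas = c(b0 = if (y[1] == 1L) 5 else -5, b1 = 0, b2 = 0),
      fit_flag = "boundary"), class = "subject_betas"))
  }
  fit <- suppressWarnings(
    glm(y ~ confidence_encoded + cost_encoded, data = design,
        family = binomial()))
  betas <- setNames(as.numeric(coef(fit)), c("b0", "b1", "b2"))
  betas[is.na(betas)] <- 0
  p <- fit$fitted.values
  separable <- all(p < 1e-8 | p > 1 - 1e-8) || any(abs(betas) > 15)
  structure(list(betas = betas,
                 fit_flag = if (separable) "separable" else "ok"),
            class = "subject_betas")
}

#' @export
print.subject_betas <- function(x, ...) {
  cat("<subject_betas>", sprintf("b0 = %.3f, b1 = %.3f, b2 = %.3f [%s]\n",
                                 x$betas[1], x$betas[2], x$betas[3], x$fit_flag))
  invisible(x)
}

#' Seek-rate inclusion filter
#'
#' Subjects enter the hierarchical analysis only when they sought
#' information on at least 5% and at most 95% of trials; both bounds are
#' inclusive. Subjects at the extremes provide no information about how
#' confidence and cost modulate their seeking.
#'
#' @param seek_rates Vector of per-subject seek rates in `[0, 1]`.
#' @return Logical inclusion mask.
#' @export
#' @examples
#' filter_inclusion(c(0.04, 0.05, 0.5, 0.95, 0.96))
filter_inclusion <- function(seek_rates) {
  if (any(!is.finite(seek_rates)) || any(seek_rates < 0 | seek_rates > 1)) {
    stop_invalid("seek rates must lie in [0, 1]")
  }
  seek_rates >= 0.05 & seek_rates <= 0.95
}
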
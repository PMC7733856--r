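#' Standardized covariate-adjusted regression with delta R-squared
#'
#' Fits an OLS regression of one subject-level outcome on a focal predictor
#' plus covariates, after z-scoring all continuous variables (so
#' coefficients are standardized betas) and dummy-coding categorical ones
#' (gender uses female as the reference level). The focal predictor's
#' contribution is quantified as `delta_R2`, the loss in R-squared when it
#' is dropped from the model. Replication-style analyses can use a
#' one-tailed p-value for the focal term, with the hypothesized direction
#' supplied explicitly (e.g. the sign observed in a first study).
#'
#' @param data Subject-level data frame.
#' @param outcome,focal Column names of the outcome and focal predictor.
#' @param covariates Character vector of covariate column names.
#' @param tails `"two"` (default) or `"one"`.
#' @param direction Hypothesized sign of the focal effect (`-1` or `1`);
#'   required when `tails = "one"`.
#'
#' @return An object of class `regression_result`: coefficient table
#'   (standardized estimates, SEs, t statistics, p-values), `r2_full`,
#'   `r2_reduced`, `delta_r2`, `n` and the focal summary.
#' @export
standardized_regression <- function(data, outcome, focal,
                                    covariates = character(),
                                    tails = c("two", "one"),
                                    direction = NULL) {
  tails <- match.arg(tails)
  if (tails == "one" && is.null(direction)) {
    stop_invalid("one-tailed tests require `direction` (the hypothesized sign)")
  }
  used <- c(outcome, focal, covariates)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop_schema(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(data[used])
  if (any(!complete.cases(df))) {
    stop_invalid("missing values in the analysis columns")
  }
  n <- nrow(df)
  if (n <= length(used) + 2L) stop_invalid("too few rows for the design")

  is_cont <- vapply(df, is.numeric, TRUE)
  zero_var <- names(df)[is_cont][vapply(df[is_cont], function(x) sd(x) == 0, TRUE)]
  if (length(zero_var)) {
    stop_invalid(paste0("zero variance in: ", paste(zero_var, collapse = ", ")))
  }
  df[is_cont] <- lapply(df[is_cont], zscore_sample)
  df[!is_cont] <- lapply(df[!is_cont], function(x) {
    if (is.character(x)) factor(x, levels = unique(c(
      intersect("female", x), sort(unique(x))))) else x
  })

  fml <- stats::reformulate(c(focal, covariates), response = outcome)
  full <- lm(fml, data = df)
  bad <- names(coef(full))[is.na(coef(full))]
  if (length(bad)) {
    abort(paste0("collinear design; aliased term(s): ",
                 paste(bad, collapse = ", ")),
          class = "metaseek_collinearity_error")
  }
  reduced <- if (length(covariates)) {
    lm(stats::reformulate(covariates, response = outcome), data = df)
  } else {
    lm(stats::reformulate("1", response = outcome), data = df)
  }
  r2_full <- summary(full)$r.squared
  r2_reduced <- summary(reduced)$r.squared

  cf <- summary(full)$coefficients
  coefs <- tibble::tibble(term = rownames(cf),
                          estimate = cf[, 1], se = cf[, 2],
                          statistic = cf[, 3], p_value = cf[, 4])
  fi <- which(coefs$term == focal)
  if (tails == "one") {
    tstat <- coefs$statistic[fi]
    dfree <- full$df.residual
    coefs$p_value[fi] <- pt(sign(direction) * tstat, dfree, lower.tail = FALSE)
  }
  structure(list(outcome = outcome, focal = focal,
                 coefficients = coefs,
                 focal_estimate = coefs$estimate[fi],
                 focal_se = coefs$se[fi],
                 focal_p = coefs$p_value[fi],
                 r2_full = r2_full, r2_reduced = r2_reduced,
                 delta_r2 = r2_full - r2_reduced,
                 n = n, tails = tails),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s ~ %s (+ %d covariate terms), n = %d\n",
              x$outcome, x$focal, nrow(x$coefficients) - 2L, x$n))
  cat(sprintf("  standardized beta = %.3f (SE %.3f), %s-tailed p = %.4g\n",
              x$focal_estimate, x$focal_se, x$tails, x$focal_p))
  cat(sprintf("  R2 = %.4f vs %.4f without focal; delta R2 = %.4f\n",
              x$r2_full, x$r2_reduced, x$delta_r2))
  invisible(x)
}

#' Polynomial fit of one factor score on another, selected by BIC
#'
#' Compares a linear, a quadratic and a combined linear-plus-quadratic OLS
#' model of `y` on `x` and selects the candidate with the lowest BIC; ties
#' break toward the model with fewer parameters.
#'
#' @param x,y Standardized factor-score vectors (length >= 10).
#' @return An object of class `poly_fit_result`: per-candidate coefficient
#'   lists and BICs, plus the `selected` label.
#' @export
#' @examples
#' fs <- generate_factor_scores(300, seed = 1)
#' polynomial_factor_fit(fs$orientation, fs$dogmatism)
polynomial_factor_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 10L) {
    stop_invalid("`x` and `y` must have equal length >= 10")
  }
  if (sd(x) == 0) stop_invalid("zero variance in `x`")
  df <- data.frame(x = x, y = y)
  fits <- list(linear = lm(y ~ x, df),
               quadratic = lm(y ~ I(x^2), df),
               combined = lm(y ~ x + I(x^2), df))
  bics <- vapply(fits, BIC, numeric(1))
  # candidates ordered by parameter count, so which.min breaks ties toward
  # the more parsimonious model
  selected <- names(bics)[which.min(bics)]
  structure(list(coefficients = lapply(fits, coef),
                 bic = bics, selected = selected, n = length(x)),
            class = "poly_fit_result")
}

#' @export
print.poly_fit_result <- function(x, ...) {
  cat("<poly_fit_result> n =", x$n, "\n")
  for (m in names(x$bic)) {
    cat(sprintf("  %-9s BIC %.2f%s\n", m, x$bic[[m]],
                if (m == x$selected) "  <- selected" else ""))
  }
  invisible(x)
}

#' Pool subject tables from several studies
#'
#' Row-concatenates subject tables with identical schemas, tags each row
#' with a study label, and re-standardizes the factor scores on the pooled
#' sample (behavioural aggregates such as seek rate remain on their natural
#' scale; [standardized_regression()] z-scores at fit time, so pooled
#' analyses are standardized on the pooled sample either way).
#'
#' @param ... Two or more subject tables (or a single list of them).
#' @param study_labels Optional labels; defaults to existing `study` columns
#'   or `study1`, `study2`, ...
#' @param restandardize Columns to re-z-score on the pooled sample.
#' @return The pooled subject table.
#' @export
pool_samples <- function(..., study_labels = NULL,
                         restandardize = c("orientation", "dogmatism",
                                           "superiority")) {
  tables <- list(...)
  if (length(tables) == 1L && is.list(tables[[1]]) &&
      !is.data.frame(tables[[1]])) {
    tables <- tables[[1]]
  }
  if (!length(tables)) stop_invalid("no subject tables supplied")
  schemas <- lapply(tables, function(t) sort(setdiff(names(t), "study")))
  for (i in seq_along(tables)[-1]) {
    if (!identical(schemas[[1]], schemas[[i]])) {
      diff_cols <- c(setdiff(schemas[[1]], schemas[[i]]),
                     setdiff(schemas[[i]], schemas[[1]]))
      stop_schema(paste0("schema mismatch between tables 1 and ", i,
                         "; differing column(s): ",
                         paste(diff_cols, collapse = ", ")))
    }
  }
  if (is.null(study_labels)) {
    study_labels <- vapply(seq_along(tables), function(i) {
      if ("study" %in% names(tables[[i]])) as.character(tables[[i]]$study[1])
      else paste0("study", i)
    }, character(1))
  }
  for (i in seq_along(tables)) tables[[i]]$study <- study_labels[i]
  pooled <- dplyr::bind_rows(tables)
  for (col in intersect(restandardize, names(pooled))) {
    pooled[[col]] <- zscore_sample(pooled[[col]])
  }
  pooled
}
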
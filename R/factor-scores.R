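#' Generate questionnaire factor scores for a synthetic cohort
#'
#' Draws per-subject scores on the three questionnaire factors — political
#' orientation, dogmatism and political belief superiority — with the
#' generative structure observed in large online samples: dogmatism is a
#' linear-plus-quadratic function of orientation (both political extremes are
#' more dogmatic), belief superiority is a negative-linear plus
#' positive-quadratic function of orientation plus a positive linear function
#' of dogmatism, and all three scores are standardized to mean 0, SD 1.
#'
#' @param n Number of subjects.
#' @param factor_structure Named list of generative coefficients; see
#'   [default_factor_structure()] for the names and defaults.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `subject_id`, `orientation`, `dogmatism`,
#'   `superiority`; each score column has sample mean 0 and SD 1.
#' @export
#' @examples
#' fs <- generate_factor_scores(200, seed = 42)
#' cor(fs$dogmatism, fs$superiority) # positive by construction
generate_factor_scores <- function(n,
                                   factor_structure = default_factor_structure(),
                                   seed = 1L) {
  n <- assert_count(n, "n")
  fs <- factor_structure
  needed <- c("dog_linear", "dog_quadratic", "dog_noise_sd",
              "sup_linear", "sup_quadratic", "sup_dogmatism", "sup_noise_sd")
  missing <- setdiff(needed, names(fs))
  if (length(missing)) {
    stop_invalid(paste0("factor_structure is missing: ",
                        paste(missing, collapse = ", ")))
  }
  if (!all(vapply(fs[needed], function(x) is.numeric(x) && is.finite(x), TRUE))) {
    stop_invalid("factor_structure coefficients must be finite numbers")
  }
  withr::with_seed(seed, {
    orientation <- rnorm(n)
    dog_raw <- fs$dog_linear * orientation +
      fs$dog_quadratic * (orientation^2 - 1) +
      rnorm(n, sd = fs$dog_noise_sd)
    dogmatism <- zscore_sample(dog_raw)
    sup_raw <- fs$sup_linear * orientation +
      fs$sup_quadratic * (orientation^2 - 1) +
      fs$sup_dogmatism * dogmatism +
      rnorm(n, sd = fs$sup_noise_sd)
    superiority <- zscore_sample(sup_raw)
    tibble::tibble(subject_id = sprintf("s%04d", seq_len(n)),
                   orientation = zscore_sample(orientation),
                   dogmatism = dogmatism,
                   superiority = superiority)
  })
}

#' Draw subject-level seek-policy coefficients from the population model
#'
#' Samples each subject's `(beta0, beta1, beta2)` from the dogmatism-shifted
#' population distributions
#' `beta_k,i ~ N(mu_B[k] + rho[k] * dogmatism_i, sigma_B[k])`, independently
#' across subjects and coefficients.
#'
#' @param pop A [population_params()] object.
#' @param dogmatism Vector of dogmatism z-scores, one per subject.
#' @param seed Integer seed.
#'
#' @return A numeric matrix with one row per subject and columns
#'   `b0`, `b1`, `b2`.
#' @export
sample_subject_params <- function(pop, dogmatism, seed = 1L) {
  stopifnot(inherits(pop, "population_params"))
  if (!length(dogmatism) || !all(is.finite(dogmatism))) {
    stop_invalid("`dogmatism` must be a non-empty finite vector")
  }
  n <- length(dogmatism)
  withr::with_seed(seed, {
    betas <- vapply(1:3, function(k) {
      rnorm(n, mean = pop$mu_B[k] + pop$rho[k] * dogmatism, sd = pop$sigma_B[k])
    }, numeric(n))
    betas <- matrix(betas, nrow = n,
                    dimnames = list(NULL, c("b0", "b1", "b2")))
    betas
  })
}
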
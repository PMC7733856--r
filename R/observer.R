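#' Simulated observer parameters
#'
#' Bundles everything that defines one simulated participant: perceptual
#' sensitivity on the log-dot-difference scale, a small lapse rate,
#' confidence criteria partitioning absolute decision evidence into three
#' confidence levels, the three seek-policy coefficients
#' (intercept, confidence slope, cost slope), a dogmatism z-score and
#' demographic covariates.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param sensitivity d-prime per unit log-dot-difference; must be positive.
#' @param lapse_rate Probability of a stimulus-independent random response,
#'   in `[0, 0.05]`.
#' @param conf_criteria Two strictly increasing positive thresholds on
#'   absolute decision evidence separating confidence levels 1/2/3.
#' @param betas Numeric 3-vector `(beta0, beta1, beta2)` of the seek policy:
#'   intercept, slope on encoded confidence, slope on the high-cost indicator.
#' @param dogmatism Dogmatism factor score (z-score).
#' @param age,gender,education Demographic covariates; `gender` is one of
#'   `"female"`, `"male"`, `"other"`.
#'
#' @return An object of class `observer_params`.
#' @export
#' @examples
#' obs <- observer_params("s1", sensitivity = 9, betas = c(0, -1, -0.8))
#' obs
observer_params <- function(subject_id,
                            sensitivity,
                            lapse_rate = 0.01,
                            conf_criteria = c(0.6, 1.3),
                            betas = c(0, -1, -0.8),
                            dogmatism = 0,
                            age = 37L,
                            gender = "female",
                            education = 3L) {
  assert_scalar_number(sensitivity, "sensitivity")
  if (sensitivity <= 0) stop_invalid("`sensitivity` must be > 0")
  assert_scalar_number(lapse_rate, "lapse_rate", min = 0, max = 0.05)
  if (length(conf_criteria) != 2L || any(conf_criteria <= 0) ||
      diff(conf_criteria) <= 0) {
    stop_invalid("`conf_criteria` must be two strictly increasing positive thresholds")
  }
  if (length(betas) != 3L || !all(is.finite(betas))) {
    stop_invalid("`betas` must be a finite numeric 3-vector")
  }
  assert_scalar_number(dogmatism, "dogmatism")
  gender <- match.arg(gender, c("female", "male", "other"))
  structure(
    list(subject_id = as.character(subject_id),
         sensitivity = sensitivity,
         lapse_rate = lapse_rate,
         conf_criteria = as.numeric(conf_criteria),
         betas = as.numeric(betas),
         dogmatism = dogmatism,
         age = as.integer(age),
         gender = gender,
         education = as.integer(education)),
    class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params> subject", x$subject_id, "\n")
  cat("  sensitivity:", format(x$sensitivity, digits = 3),
      " lapse:", format(x$lapse_rate, digits = 2), "\n")
  cat("  conf criteria:", paste(format(x$conf_criteria, digits = 3),
                                collapse = ", "), "\n")
  cat("  seek betas: b0 =", format(x$betas[1], digits = 3),
      " b1 =", format(x$betas[2], digits = 3),
      " b2 =", format(x$betas[3], digits = 3), "\n")
  cat("  dogmatism:", format(x$dogmatism, digits = 3), "\n")
  invisible(x)
}

#' Population distribution of seek-policy parameters
#'
#' Group-level means, spreads and covariate-embedding slopes for the three
#' seek-policy coefficients. Subject-level coefficients are drawn as
#' `beta_k,i ~ N(mu_B[k] + rho[k] * dogmatism_i, sigma_B[k])`: the prior mean
#' shifts linearly with each subject's dogmatism score, so `rho` captures the
#' association between dogmatism and each coefficient.
#'
#' @param mu_B Numeric 3-vector of population means.
#' @param sigma_B Numeric 3-vector of positive population SDs.
#' @param rho Numeric 3-vector of embedding slopes (effect of a 1-SD increase
#'   in dogmatism on each coefficient's mean).
#'
#' @return An object of class `population_params`.
#' @export
#' @examples
#' population_params(mu_B = c(0, -1, -0.8), sigma_B = c(1, 0.5, 0.5),
#'                   rho = c(-0.24, 0.15, 0))
population_params <- function(mu_B = c(0, -1, -0.8),
                              sigma_B = c(1, 0.5, 0.5),
                              rho = c(0, 0, 0)) {
  if (length(mu_B) != 3L || length(sigma_B) != 3L || length(rho) != 3L) {
    stop_invalid("`mu_B`, `sigma_B` and `rho` must each have length 3")
  }
  if (!all(is.finite(c(mu_B, sigma_B, rho)))) {
    stop_invalid("population parameters must be finite")
  }
  if (any(sigma_B <= 0)) stop_invalid("all `sigma_B` must be > 0")
  structure(list(mu_B = as.numeric(mu_B), sigma_B = as.numeric(sigma_B),
                 rho = as.numeric(rho)),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  m <- rbind(mu_B = x$mu_B, sigma_B = x$sigma_B, rho = x$rho)
  colnames(m) <- c("b0", "b1", "b2")
  cat("<population_params>\n")
  print(round(m, 3))
  invisible(x)
}

#' Cohort simulation configuration
#'
#' Defines a complete synthetic study: cohort size, the block structure of
#' the seek task (4 blocks of 25 trials by default), the assignment of the
#' two information costs to blocks, the population distribution of
#' seek-policy parameters, the factor-score structure, observer-parameter
#' distributions and the post-decision evidence multiplier.
#'
#' @param n_subjects Number of subjects.
#' @param n_blocks,trials_per_block Block structure; the product is the
#'   number of main-task trials per subject.
#' @param cost_schedule Cost in points charged for seeking in each block;
#'   must use exactly the values 5 and 20.
#' @param population A [population_params()] object.
#' @param factor_structure Named list of coefficients for the factor-score
#'   generator; see [generate_factor_scores()].
#' @param sensitivity_meanlog,sensitivity_sdlog Log-normal distribution of
#'   perceptual sensitivity across subjects.
#' @param lapse_max Upper bound of the uniform lapse-rate distribution.
#' @param conf_criteria Population-level confidence criteria; per-subject
#'   criteria are jittered around these.
#' @param criterion_jitter_sd SD of the multiplicative log-normal jitter
#'   applied to the confidence criteria per subject.
#' @param postdecision_multiplier Multiplier applied to the calibrated
#'   log-stimulus strength for the post-decision (sought) stimulus; the
#'   additional evidence is always helpful and stronger than the first.
#' @param calibration_trials Number of staircase trials per subject.
#' @param seed Integer seed making the whole cohort reproducible.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 50L,
                          n_blocks = 4L,
                          trials_per_block = 25L,
                          cost_schedule = c(5L, 20L, 5L, 20L),
                          population = population_params(),
                          factor_structure = default_factor_structure(),
                          sensitivity_meanlog = log(9),
                          sensitivity_sdlog = 0.25,
                          lapse_max = 0.02,
                          conf_criteria = c(0.6, 1.3),
                          criterion_jitter_sd = 0.15,
                          postdecision_multiplier = 3,
                          calibration_trials = 120L,
                          seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  n_blocks <- assert_count(n_blocks, "n_blocks")
  trials_per_block <- assert_count(trials_per_block, "trials_per_block")
  if (length(cost_schedule) != n_blocks) {
    stop_invalid("`cost_schedule` must give one cost per block")
  }
  if (!setequal(unique(cost_schedule), c(5L, 20L))) {
    stop_invalid("`cost_schedule` must use exactly the cost levels 5 and 20")
  }
  stopifnot(inherits(population, "population_params"))
  assert_scalar_number(postdecision_multiplier, "postdecision_multiplier")
  if (postdecision_multiplier <= 1) {
    stop_invalid("`postdecision_multiplier` must exceed 1 (the second look is always stronger)")
  }
  structure(
    list(n_subjects = n_subjects,
         n_blocks = n_blocks,
         trials_per_block = trials_per_block,
         trials_per_subject = n_blocks * trials_per_block,
         cost_schedule = as.integer(cost_schedule),
         population = population,
         factor_structure = factor_structure,
         sensitivity_meanlog = sensitivity_meanlog,
         sensitivity_sdlog = sensitivity_sdlog,
         lapse_max = lapse_max,
         conf_criteria = as.numeric(conf_criteria),
         criterion_jitter_sd = criterion_jitter_sd,
         postdecision_multiplier = postdecision_multiplier,
         calibration_trials = assert_count(calibration_trials, "calibration_trials", min = 20L),
         seed = assert_count(seed, "seed", min = 0L)),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>", x$n_subjects, "subjects,",
      x$n_blocks, "blocks x", x$trials_per_block, "trials\n")
  cat("  cost schedule:", paste(x$cost_schedule, collapse = "/"),
      " post-decision multiplier:", x$postdecision_multiplier, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Default factor-score structure
#'
#' Coefficients of the generative relationships among the three questionnaire
#' factors: political orientation, dogmatism and political belief superiority.
#' Dogmatism rises linearly and quadratically with orientation (both extremes
#' more dogmatic, more so on the right); belief superiority falls linearly and
#' rises quadratically with orientation and rises with dogmatism. Residual
#' noise SDs are on the scale of the standardized factors.
#'
#' @return Named list of coefficients consumed by [generate_factor_scores()].
#' @export
default_factor_structure <- function() {
  list(dog_linear = 0.20, dog_quadratic = 0.36, dog_noise_sd = 0.85,
       sup_linear = -0.33, sup_quadratic = 0.38, sup_dogmatism = 0.20,
       sup_noise_sd = 0.80)
}
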
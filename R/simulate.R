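# Canonical encoding of the 3-level confidence rating used by the generative
# seek policy: centered at level 2 and scaled by sqrt(2/3), the population SD
# of a uniform 3-point variable, so that equally frequent levels map to
# {-1.2247, 0, +1.2247} — the same values encode_predictors() produces on
# balanced data.
encode_conf_canonical <- function(level) (level - 2) / sqrt(2 / 3)

#' Simulate main-task trials for one observer
#'
#' Generates `n_trials` trials of the costed information-seeking task for a
#' single observer at a fixed calibrated dot difference. Each trial draws a
#' decision variable `x ~ N(d * side, 1)` (with
#' `d = sensitivity * log(1 + delta/313)/sqrt(2)`), takes the initial choice
#' as its sign (with a small lapse probability of responding at random),
#' reads the confidence level off `|x|` against the observer's criteria,
#' draws the seek decision from the logistic seek policy
#' `P(seek) = plogis(b0 + b1 * conf + b2 * cost)`, and — when information is
#' sought — adds a second, stronger evidence draw
#' `x2 ~ N(multiplier * d * side, 1)` before the final choice. Without
#' seeking the final choice repeats the initial one. Points follow the task
#' payoff: 100 for a correct final decision, 0 otherwise, minus the cost
#' when information was sought.
#'
#' @param observer An [observer_params()] object.
#' @param dot_difference Calibrated dot difference (`>= 1`).
#' @param cost_points Cost of seeking per trial: a scalar or length
#'   `n_trials` vector with values in `{5, 20}`.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param postdecision_multiplier Multiplier on the calibrated log-strength
#'   for the sought stimulus (must exceed 1).
#' @param block Optional block index per trial (stored in the output).
#'
#' @return A tibble with one row per trial, in the trial-table schema (see
#'   [read_trials()]): choices, confidence levels and 6-point codes, the
#'   seek decision, correctness flags and points.
#' @export
simulate_trials <- function(observer, dot_difference, cost_points,
                            n_trials = length(cost_points), seed = 1L,
                            postdecision_multiplier = 3, block = NULL) {
  stopifnot(inherits(observer, "observer_params"))
  n_trials <- assert_count(n_trials, "n_trials")
  if (dot_difference < 1) stop_invalid("`dot_difference` must be >= 1")
  cost_points <- as.integer(rep_len(cost_points, n_trials))
  if (!all(cost_points %in% c(5L, 20L))) {
    stop_invalid("`cost_points` values must be 5 or 20")
  }
  if (postdecision_multiplier <= 1) {
    stop_invalid("`postdecision_multiplier` must exceed 1")
  }
  block <- if (is.null(block)) rep(1L, n_trials) else as.integer(rep_len(block, n_trials))

  d <- observer$sensitivity * log(1 + dot_difference / 313) / sqrt(2)
  cc <- observer$conf_criteria
  b <- observer$betas

  withr::with_seed(seed, {
    side <- sample(c(-1L, 1L), n_trials, replace = TRUE)
    x <- rnorm(n_trials, mean = d * side, sd = 1)
    choice <- sign(x)
    choice[choice == 0] <- 1L
    lapsed <- runif(n_trials) < observer$lapse_rate
    choice[lapsed] <- sample(c(-1L, 1L), sum(lapsed), replace = TRUE)
    conf_level <- 1L + (abs(x) >= cc[1]) + (abs(x) >= cc[2])

    cost_ind <- as.numeric(cost_points == 20L)
    p_seek <- plogis(b[1] + b[2] * encode_conf_canonical(conf_level) +
                       b[3] * cost_ind)
    sought <- runif(n_trials) < p_seek

    x_final <- x
    x2 <- rnorm(n_trials, mean = postdecision_multiplier * d * side, sd = 1)
    x_final[sought] <- x[sought] + x2[sought]
    final_choice <- ifelse(sought, sign(x_final), choice)
    final_choice[final_choice == 0] <- 1L
    final_conf <- ifelse(sought,
                         1L + (abs(x_final) >= cc[1]) + (abs(x_final) >= cc[2]),
                         conf_level)

    initial_correct <- choice == side
    final_correct <- final_choice == side
    tibble::tibble(
      subject_id = observer$subject_id,
      block = block,
      trial_index = seq_len(n_trials),
      cost_points = cost_points,
      dot_difference = as.integer(dot_difference),
      correct_side = ifelse(side == 1L, "right", "left"),
      initial_choice = ifelse(choice == 1L, "right", "left"),
      initial_conf_level = as.integer(conf_level),
      initial_conf_code6 = conf_code6(choice, conf_level),
      sought = sought,
      final_choice = ifelse(final_choice == 1L, "right", "left"),
      final_conf_level = as.integer(final_conf),
      initial_correct = initial_correct,
      final_correct = final_correct,
      points = as.integer(100L * final_correct - cost_points * sought))
  })
}

#' @rdname simulate_trials
#' @export
simulate_trial <- function(observer, dot_difference, cost_points, seed = 1L,
                           postdecision_multiplier = 3) {
  simulate_trials(observer, dot_difference, cost_points, n_trials = 1L,
                  seed = seed, postdecision_multiplier = postdecision_multiplier)
}

# Signed six-point confidence code: "sure left" = 1 ... "sure right" = 6.
# Left choices map levels 3/2/1 to codes 1/2/3; right choices to 4/5/6.
conf_code6 <- function(choice, level) {
  as.integer(ifelse(choice == 1L, 3L + level, 4L - level))
}

#' Simulate a complete synthetic cohort
#'
#' Generates a full synthetic study from a [cohort_config()]: factor scores
#' for every subject, seek-policy coefficients drawn from the
#' dogmatism-shifted population distributions, demographic covariates, a
#' per-subject staircase calibration of task difficulty, and the full block
#' structure of main-task trials. Everything derives deterministically from
#' the config seed.
#'
#' @param config A [cohort_config()] object.
#' @param study Study label stored in both output tables.
#'
#' @return A list with elements `trials` (one row per trial, trial-table
#'   schema) and `subjects` (one row per subject, subject-table schema with
#'   factor scores, demographics, calibrated difficulty and behavioural
#'   aggregates).
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(n_subjects = 10, seed = 3))
#' mean(cohort$trials$initial_correct) # close to the ~0.71 calibration target
#' }
simulate_cohort <- function(config = cohort_config(), study = "study1") {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects

  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max - 1L, 4L + 2L * n))
  factors <- generate_factor_scores(n, config$factor_structure, seed = seeds[1])
  betas <- sample_subject_params(config$population, factors$dogmatism,
                                 seed = seeds[2])

  attrs <- withr::with_seed(seeds[3], {
    tibble::tibble(
      sensitivity = exp(rnorm(n, config$sensitivity_meanlog,
                              config$sensitivity_sdlog)),
      lapse_rate = runif(n, 0, config$lapse_max),
      crit1 = config$conf_criteria[1] *
        exp(rnorm(n, 0, config$criterion_jitter_sd)),
      crit_gap = (config$conf_criteria[2] - config$conf_criteria[1]) *
        exp(rnorm(n, 0, config$criterion_jitter_sd)))
  })
  covars <- withr::with_seed(seeds[4], {
    tibble::tibble(
      age = pmin(81L, pmax(18L, as.integer(round(rnorm(n, 36.6, 11.4))))),
      gender = sample(c("female", "male", "other"), n, replace = TRUE,
                      prob = c(0.50, 0.49, 0.01)),
      education = sample(1:5, n, replace = TRUE,
                         prob = c(0.05, 0.25, 0.35, 0.25, 0.10)))
  })

  cost_per_trial <- rep(config$cost_schedule, each = config$trials_per_block)
  block_per_trial <- rep(seq_len(config$n_blocks), each = config$trials_per_block)

  trial_list <- vector("list", n)
  calibrated <- integer(n)
  for (i in seq_len(n)) {
    obs <- observer_params(
      subject_id = factors$subject_id[i],
      sensitivity = attrs$sensitivity[i],
      lapse_rate = attrs$lapse_rate[i],
      conf_criteria = c(attrs$crit1[i], attrs$crit1[i] + attrs$crit_gap[i]),
      betas = betas[i, ],
      dogmatism = factors$dogmatism[i],
      age = covars$age[i], gender = covars$gender[i],
      education = covars$education[i])
    calibrated[i] <- calibrate_staircase(obs, n_trials = config$calibration_trials,
                                         seed = seeds[4L + i])
    trial_list[[i]] <- simulate_trials(
      obs, calibrated[i], cost_per_trial,
      n_trials = config$trials_per_subject,
      seed = seeds[4L + n + i],
      postdecision_multiplier = config$postdecision_multiplier,
      block = block_per_trial)
  }
  trials <- dplyr::bind_rows(trial_list)
  trials$study <- study
  trials <- dplyr::relocate(trials, "study")

  subject_info <- dplyr::bind_cols(
    factors,
    covars,
    tibble::tibble(calibrated_dot_difference = calibrated))
  subject_info$study <- study
  subjects <- aggregate_subjects(trials, subject_info)

  if (anyNA(trials) || anyNA(subjects)) {
    abort("internal consistency error: NaN/NA in simulated tables",
          class = "metaseek_internal_error")
  }
  list(trials = trials, subjects = subjects)
}
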
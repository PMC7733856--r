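trial_schema <- c(
  study = "character", subject_id = "character", block = "integer",
  trial_index = "integer", cost_points = "integer", dot_difference = "integer",
  correct_side = "character", initial_choice = "character",
  initial_conf_level = "integer", initial_conf_code6 = "integer",
  sought = "logical", final_choice = "character",
  final_conf_level = "integer", initial_correct = "logical",
  final_correct = "logical", points = "integer")

subject_schema <- c(
  subject_id = "character", study = "character", orientation = "numeric",
  dogmatism = "numeric", superiority = "numeric", age = "integer",
  gender = "character", education = "integer", seek_rate = "numeric",
  initial_accuracy = "numeric", final_accuracy = "numeric",
  mean_confidence = "numeric", calibrated_dot_difference = "integer",
  total_points = "integer", n_trials = "integer")

validate_columns <- function(tbl, schema, what) {
  missing_cols <- setdiff(names(schema), names(tbl))
  if (length(missing_cols)) {
    stop_schema(sprintf("%s table is missing column(s): %s", what,
                        paste(missing_cols, collapse = ", ")))
  }
  if (any(!nzchar(tbl$subject_id) | is.na(tbl$subject_id))) {
    stop_schema(sprintf("%s table has empty subject ids", what))
  }
  invisible(tbl)
}

readr_types <- function(schema) {
  map <- c(character = "c", integer = "i", numeric = "d", logical = "l")
  paste(map[schema], collapse = "")
}

#' Read and write trial tables
#'
#' CSV serialization of the trial table (one row per task trial). Reading
#' validates the schema: every required column must be present with the
#' right type, subject ids must be non-empty, `(subject_id, trial_index)`
#' must be unique, costs must be 5 or 20, confidence levels in 1..3, and
#' the points identity `points = 100 * final_correct - cost * sought` must
#' hold on every row. Round-trips are lossless.
#'
#' @param path CSV file path.
#' @param trials A trial table as produced by [simulate_cohort()].
#' @return `read_trials()` returns the validated tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = "?"),
                         progress = FALSE, show_col_types = FALSE)
  validate_columns(tbl, trial_schema, "trial")
  for (col in names(trial_schema)) {
    tbl[[col]] <- switch(trial_schema[[col]],
                         character = as.character(tbl[[col]]),
                         integer = as.integer(tbl[[col]]),
                         numeric = as.numeric(tbl[[col]]),
                         logical = as.logical(tbl[[col]]))
    if (anyNA(tbl[[col]])) {
      stop_schema(sprintf("column `%s` has missing or untypeable values (first at row %d)",
                          col, which(is.na(tbl[[col]]))[1]))
    }
  }
  dup <- duplicated(tbl[c("subject_id", "trial_index")])
  if (any(dup)) {
    stop_schema(sprintf("duplicate (subject_id, trial_index) at row %d",
                        which(dup)[1]))
  }
  if (!all(tbl$cost_points %in% c(5L, 20L))) {
    stop_schema("cost_points must be 5 or 20")
  }
  if (!all(tbl$initial_conf_level %in% 1:3)) {
    stop_schema("initial_conf_level must be in 1..3")
  }
  bad <- which(tbl$points !=
                 100L * tbl$final_correct - tbl$cost_points * tbl$sought)
  if (length(bad)) {
    stop_schema(sprintf("points identity violated at row %d", bad[1]))
  }
  tbl[names(trial_schema)]
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  validate_columns(trials, trial_schema, "trial")
  readr::write_csv(trials[names(trial_schema)], path, progress = FALSE)
  invisible(path)
}

#' Read and write subject tables
#'
#' CSV serialization of the subject table (one row per subject: factor
#' scores, demographics, calibrated difficulty and behavioural aggregates).
#' Reading validates the schema and the range constraints (rates and
#' accuracies in `[0, 1]`, one row per subject).
#'
#' @param path CSV file path.
#' @param subjects A subject table.
#' @return `read_subjects()` returns the validated tibble; `write_subjects()`
#'   returns `path` invisibly.
#' @export
read_subjects <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = "?"),
                         progress = FALSE, show_col_types = FALSE)
  validate_columns(tbl, subject_schema, "subject")
  for (col in names(subject_schema)) {
    tbl[[col]] <- switch(subject_schema[[col]],
                         character = as.character(tbl[[col]]),
                         integer = as.integer(tbl[[col]]),
                         numeric = as.numeric(tbl[[col]]),
                         logical = as.logical(tbl[[col]]))
  }
  if (anyNA(tbl)) stop_schema("subject table contains missing values")
  if (any(duplicated(tbl$subject_id))) {
    stop_schema("duplicate subject_id in subject table")
  }
  rates <- c(tbl$seek_rate, tbl$initial_accuracy, tbl$final_accuracy)
  if (any(rates < 0 | rates > 1)) {
    stop_schema("seek_rate and accuracies must lie in [0, 1]")
  }
  tbl[names(subject_schema)]
}

#' @rdname read_subjects
#' @export
write_subjects <- function(subjects, path) {
  validate_columns(subjects, subject_schema, "subject")
  readr::write_csv(subjects[names(subject_schema)], path, progress = FALSE)
  invisible(path)
}

#' Aggregate a trial table to subject-level behaviour
#'
#' Computes each subject's seek rate, initial and final accuracy, mean
#' initial confidence level, calibrated dot difference and total points,
#' and joins per-subject covariates (factor scores, demographics) when
#' supplied. Subjects present in `subject_info` but without any trials are
#' dropped with a warning.
#'
#' @param trials Trial table.
#' @param subject_info Optional per-subject covariate table with
#'   `subject_id` and any of: `study`, `orientation`, `dogmatism`,
#'   `superiority`, `age`, `gender`, `education`,
#'   `calibrated_dot_difference`.
#' @return A subject table (one row per subject).
#' @export
aggregate_subjects <- function(trials, subject_info = NULL) {
  validate_columns(trials, trial_schema[setdiff(names(trial_schema), "study")],
                   "trial")
  agg <- trials |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      study = if ("study" %in% names(trials)) .data$study[1] else "study1",
      seek_rate = mean(.data$sought),
      initial_accuracy = mean(.data$initial_correct),
      final_accuracy = mean(.data$final_correct),
      mean_confidence = mean(.data$initial_conf_level),
      calibrated_dot_difference = as.integer(.data$dot_difference[1]),
      total_points = as.integer(sum(.data$points)),
      n_trials = dplyr::n(),
      .groups = "drop")
  if (!is.null(subject_info)) {
    no_trials <- setdiff(subject_info$subject_id, agg$subject_id)
    if (length(no_trials)) {
      warn(paste0("dropping subject(s) without trials: ",
                  paste(utils::head(no_trials, 5), collapse = ", ")))
    }
    keep <- setdiff(names(subject_info), c("study", "calibrated_dot_difference"))
    agg <- dplyr::inner_join(agg, subject_info[keep], by = "subject_id")
  } else {
    # schema columns not derivable from trials alone
    agg$orientation <- NA_real_; agg$dogmatism <- NA_real_
    agg$superiority <- NA_real_; agg$age <- NA_integer_
    agg$gender <- NA_character_; agg$education <- NA_integer_
  }
  agg[names(subject_schema)]
}
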
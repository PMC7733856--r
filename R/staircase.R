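#' Psychometric accuracy of an observer at a given dot difference
#'
#' Maps a dot difference (target minus the 313-dot baseline) to expected
#' initial-decision accuracy under the observer's psychometric function.
#' Evidence follows a 2AFC differencing model: the decision variable is
#' `x ~ N(d, 1)` with `d = sensitivity * log(1 + delta/313) / sqrt(2)`, so
#' accuracy is `lapse/2 + (1 - lapse) * pnorm(d)`. Weber-like log scaling on
#' the 313-dot baseline keeps a unit of sensitivity comparable across the
#' dot-difference range.
#'
#' @param observer An [observer_params()] object.
#' @param dot_difference Integer dot difference(s), `>= 1`.
#' @return Probability of a correct initial decision (vectorized).
#' @export
psychometric_accuracy <- function(observer, dot_difference) {
  stopifnot(inherits(observer, "observer_params"))
  if (any(dot_difference < 1)) stop_invalid("`dot_difference` must be >= 1")
  d <- observer$sensitivity * log(1 + dot_difference / 313) / sqrt(2)
  observer$lapse_rate / 2 + (1 - observer$lapse_rate) * pnorm(d)
}

# Largest admissible dot difference: the target square has 625 cells and the
# baseline holds 313 dots, leaving at most 312 extra dots.
MAX_DOT_DIFFERENCE <- 312L

#' Adaptive staircase calibration of task difficulty
#'
#' Runs a two-down-one-up adaptive staircase on the log dot difference
#' against the observer's psychometric function, mimicking the
#' feedback-based calibration phase that precedes the main task. Difficulty
#' increases (dot difference shrinks) after two consecutive correct
#' responses and decreases after each error; the step size halves after the
#' first three reversals; the returned difficulty is the mean of all
#' reversal points after the third (all reversals if three or fewer
#' occurred). The two-down-one-up rule converges where accuracy is
#' `sqrt(1/2) ~ 70.7%`, i.e. close to the ~71% the task targets. Note that a
#' single 120-trial staircase estimates that point with an irreducible
#' accuracy-scale spread of several percentage points (the binomial
#' information in 120 trials); averaging over replicate calibrations, as
#' the multi-subject cohort effectively does, recovers the 70.7%
#' convergence point.
#'
#' @param observer An [observer_params()] object.
#' @param n_trials Number of calibration trials (default 120).
#' @param seed Integer seed.
#' @param start_difference Dot difference at the first trial.
#' @param initial_step Initial step size on the log dot-difference scale.
#' @param accuracy_fn Optional override: a function `delta -> P(correct)`
#'   replacing the observer's psychometric function (used for testing the
#'   staircase logic against degenerate observers).
#'
#' @return The calibrated integer dot difference (`>= 1`).
#' @export
#' @examples
#' obs <- observer_params("s1", sensitivity = 9)
#' delta <- calibrate_staircase(obs, seed = 7)
#' psychometric_accuracy(obs, delta) # close to 0.707
calibrate_staircase <- function(observer, n_trials = 120L, seed = 1L,
                                start_difference = 60L, initial_step = 0.5,
                                accuracy_fn = NULL) {
  stopifnot(inherits(observer, "observer_params"))
  n_trials <- assert_count(n_trials, "n_trials", min = 20L)
  p_of <- accuracy_fn %||% function(delta) psychometric_accuracy(observer, delta)
  if (p_of(MAX_DOT_DIFFERENCE) < 0.6) {
    abort(sprintf(
      "calibration failed for subject %s: accuracy %.2f below 0.6 even at the maximum dot difference (%d)",
      observer$subject_id, p_of(MAX_DOT_DIFFERENCE), MAX_DOT_DIFFERENCE),
      class = "metaseek_calibration_failure")
  }
  log_min <- log(1); log_max <- log(MAX_DOT_DIFFERENCE)
  withr::with_seed(seed, {
    L <- log(start_difference)
    step <- initial_step
    n_correct_run <- 0L
    last_direction <- 0L  # +1 harder (down), -1 easier (up)
    reversal_points <- numeric(0)
    for (t in seq_len(n_trials)) {
      delta <- max(1L, min(MAX_DOT_DIFFERENCE, as.integer(round(exp(L)))))
      correct <- runif(1) < p_of(delta)
      if (correct) {
        n_correct_run <- n_correct_run + 1L
        direction <- 0L
        if (n_correct_run == 2L) {
          n_correct_run <- 0L
          direction <- 1L
          L <- L - step
        }
      } else {
        n_correct_run <- 0L
        direction <- -1L
        L <- L + step
      }
      if (direction != 0L) {
        if (last_direction != 0L && direction != last_direction) {
          reversal_points <- c(reversal_points, L)
          if (length(reversal_points) == 3L) step <- step / 2
        }
        last_direction <- direction
      }
      L <- max(log_min, min(log_max, L))
    }
    L_final <- if (length(reversal_points) > 3L) {
      mean(reversal_points[-(1:3)])
    } else if (length(reversal_points)) {
      mean(reversal_points)
    } else L
    max(1L, min(MAX_DOT_DIFFERENCE, as.integer(round(exp(L_final)))))
  })
}
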
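#' Seek-rate curves for high-dogmatism vs remaining subjects
#'
#' Splits subjects at a dogmatism quantile (default: the 10% most dogmatic
#' against the remainder) and returns, per confidence level and group, the
#' model-predicted seek rates — each subject's logistic seek probability
#' averaged over both cost levels — and, when a trial table is supplied, the
#' empirical per-subject seek rates. Summaries are the group mean plus
#' median and quartiles across subjects.
#'
#' @param betas Matrix of fitted subject coefficients (rows = subjects,
#'   columns `b0`, `b1`, `b2`), e.g. `fit$subject_means` from
#'   [fit_hierarchical()] or stacked [fit_subject_mle()] estimates.
#' @param dogmatism Dogmatism score per subject, aligned with `betas` rows
#'   (or named by subject id when `betas` has row names).
#' @param trials Optional trial table for empirical curves.
#' @param split_quantile Quantile defining the high-dogmatism group.
#'
#' @return A tibble with one row per (group, confidence level):
#'   `predicted_mean`, `predicted_median`, `predicted_q25`, `predicted_q75`
#'   and, with trials, `empirical_median`, `empirical_q25`, `empirical_q75`,
#'   plus `n_subjects`.
#' @export
predict_group_curves <- function(betas, dogmatism, trials = NULL,
                                 split_quantile = 0.90) {
  betas <- as.matrix(betas)
  n <- nrow(betas)
  if (n < 10L) {
    abort(sprintf("need at least 10 subjects for a group split, got %d", n),
          class = "metaseek_insufficient_sample")
  }
  if (length(dogmatism) != n) {
    stop_invalid("`dogmatism` must align with the rows of `betas`")
  }
  cutoff <- quantile(dogmatism, split_quantile, names = FALSE)
  group <- ifelse(dogmatism > cutoff, "high_dogmatism", "remainder")

  levels3 <- 1:3
  pred <- vapply(levels3, function(lev) {
    e <- encode_conf_canonical(lev)
    # average over both cost levels (low = 0, high = 1)
    rowMeans(cbind(plogis(betas[, 1] + betas[, 2] * e),
                   plogis(betas[, 1] + betas[, 2] * e + betas[, 3])))
  }, numeric(n))

  emp <- NULL
  if (!is.null(trials)) {
    ids <- rownames(betas) %||% unique(as.character(trials$subject_id))
    emp <- matrix(NA_real_, n, 3)
    for (lev in levels3) {
      sub <- trials[trials$initial_conf_level == lev, ]
      # per-subject rate averaged over the two cost levels where observed
      rate <- tapply(as.numeric(sub$sought),
                     list(as.character(sub$subject_id), sub$cost_points),
                     mean)
      per_subj <- rowMeans(rate, na.rm = TRUE)
      emp[, lev] <- per_subj[ids]
    }
  }

  out <- lapply(c("high_dogmatism", "remainder"), function(g) {
    sel <- group == g
    lapply(levels3, function(lev) {
      row <- tibble::tibble(
        group = g, confidence_level = lev, n_subjects = sum(sel),
        predicted_mean = mean(pred[sel, lev]),
        predicted_median = median(pred[sel, lev]),
        predicted_q25 = quantile(pred[sel, lev], 0.25, names = FALSE),
        predicted_q75 = quantile(pred[sel, lev], 0.75, names = FALSE))
      if (!is.null(emp)) {
        e <- emp[sel, lev]
        row$empirical_median <- median(e, na.rm = TRUE)
        row$empirical_q25 <- quantile(e, 0.25, na.rm = TRUE, names = FALSE)
        row$empirical_q75 <- quantile(e, 0.75, na.rm = TRUE, names = FALSE)
      }
      row
    })
  })
  dplyr::bind_rows(unlist(out, recursive = FALSE))
}

#' Plot group seek-rate curves
#'
#' Line plot of predicted group seek rates by confidence level from
#' [predict_group_curves()]. Requires ggplot2.
#'
#' @param curves Output of [predict_group_curves()].
#' @return A ggplot object.
#' @export
plot_group_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$confidence_level,
                               y = .data$predicted_mean,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Initial confidence level", y = "P(seek information)",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
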
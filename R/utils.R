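#' @importFrom stats rnorm rbinom runif sd lm coef vcov pnorm plogis qnorm
#' @importFrom stats BIC pt quantile median complete.cases model.matrix glm
#' @importFrom stats binomial setNames var update
#' @importFrom rlang abort warn .data
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_invalid <- function(msg, ...) {
  abort(msg, class = "metaseek_invalid_argument", ...)
}

stop_schema <- function(msg, ...) {
  abort(msg, class = "metaseek_schema_error", ...)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop_invalid(sprintf("`%s` must be a single finite number in [%s, %s]",
                         name, format(min), format(max)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x)) {
    stop_invalid(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# Population (1/n) standardization: equally frequent levels {1,2,3} map to
# exactly +/- sqrt(3/2) = 1.2247, matching the simulator's canonical encoding.
zscore_pop <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) return(rep(0, length(x)))
  (x - mu) / s
}

zscore_sample <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
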
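jags_seek_model <- "
model {
  for (t in 1:T) {
    y[t] ~ dbin(p[t], n[t])
    logit(p[t]) <- b0[s[t]] + b1[s[t]] * conf[t] + b2[s[t]] * cost[t]
  }
  for (i in 1:N) {
    b0[i] ~ dnorm(mu[1] + rho[1] * dog[i], tau[1])
    b1[i] ~ dnorm(mu[2] + rho[2] * dog[i], tau[2])
    b2[i] ~ dnorm(mu[3] + rho[3] * dog[i], tau[3])
  }
  for (k in 1:3) {
    mu[k]  ~ dnorm(0, 0.04)
    rho[k] ~ dnorm(0, 0.04)
    sigma[k] ~ dnorm(0, 0.16) T(0,)
    tau[k] <- pow(sigma[k], -2)
  }
}"

#' Hierarchical Bayesian fit of the seek model with embedded dogmatism
#'
#' Estimates the trial-by-trial logistic seek model jointly for all
#' subjects, with each subject's coefficients drawn from group-level Normal
#' priors whose means shift linearly with the subject's dogmatism score:
#' `beta_k,i ~ N(mu_B[k] + rho[k] * dogmatism_i, sigma_B[k])`. Embedding the
#' covariate in the prior (rather than correlating point estimates with it
#' afterwards) propagates estimation uncertainty into the association
#' parameters `rho`, whose 95% credible intervals provide the significance
#' test. Hyperpriors are weakly informative on the logit scale:
#' `Normal(0, 5)` on each mean and embedding slope, `Half-Normal(0, 2.5)`
#' on each spread. Sampling uses JAGS; trials are aggregated into binomial
#' counts per (subject, confidence, cost) cell, which leaves the likelihood
#' unchanged.
#'
#' @param design Design table from [encode_predictors()]. Subjects should
#'   already satisfy the 5%-95% seek-rate inclusion filter
#'   ([filter_inclusion()]); at least 20 subjects are required.
#' @param dogmatism Named numeric vector of dogmatism scores covering every
#'   subject id in `design`; z-scored internally before embedding.
#' @param n_chains,n_adapt,n_warmup,n_draws MCMC settings: number of chains,
#'   adaptation steps, warmup (burn-in) iterations and kept draws per chain.
#' @param rhat_threshold Convergence threshold on the rank-normalized
#'   split-R-hat; exceeding it raises a warning, not an error.
#' @param seed Integer seed (per-chain RNGs are derived from it).
#'
#' @return An object of class `seek_posterior` with elements `summary`
#'   (one row per parameter: posterior mean, SD, 2.5%/97.5% quantiles,
#'   R-hat, effective sample size), `subject_ids`, `n_chains`, `n_draws`,
#'   `group_draws` (matrix of draws for the nine group-level parameters) and
#'   `subject_means` (posterior-mean coefficients per subject).
#' @seealso [summarize_embedding()] for the credible-interval decision on
#'   each embedding slope.
#' @export
fit_hierarchical <- function(design, dogmatism,
                             n_chains = 4L, n_adapt = 500L,
                             n_warmup = 1000L, n_draws = 1000L,
                             rhat_threshold = 1.01, seed = 1L) {
  ids <- unique(design$subject_id)
  n_subj <- length(ids)
  if (n_subj < 20L) {
    stop_invalid(sprintf("need at least 20 subjects, got %d", n_subj))
  }
  if (is.null(names(dogmatism))) {
    if (length(dogmatism) != n_subj) {
      stop_invalid("`dogmatism` must be named by subject id or aligned with the unique subjects")
    }
    names(dogmatism) <- ids
  }
  missing_dog <- setdiff(ids, names(dogmatism))
  if (length(missing_dog)) {
    stop_invalid(paste0("no dogmatism score for subject(s): ",
                        paste(utils::head(missing_dog, 5), collapse = ", ")))
  }
  dog <- zscore_sample(as.numeric(dogmatism[ids]))
  if (length(unique(dog)) < 2L) {
    abort("embedding unidentifiable: fewer than 2 distinct dogmatism values",
          class = "metaseek_embedding_unidentifiable")
  }

  # binomial aggregation over identical predictor cells (same likelihood)
  idx <- match(design$subject_id, ids)
  key <- paste(idx, design$confidence_encoded, design$cost_encoded, sep = "\r")
  agg <- rowsum(cbind(y = as.numeric(design$sought), n = 1), key, reorder = FALSE)
  first <- !duplicated(key)
  dat <- list(T = nrow(agg), N = n_subj,
              y = as.integer(agg[, "y"]), n = as.integer(agg[, "n"]),
              s = idx[first],
              conf = design$confidence_encoded[first],
              cost = design$cost_encoded[first],
              dog = dog)

  chain_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_chains))
  inits <- lapply(chain_seeds, function(s) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s,
         mu = c(0, 0, 0), rho = c(0, 0, 0), sigma = c(1, 1, 1))
  })
  jm <- rjags::jags.model(textConnection(jags_seek_model), data = dat,
                          inits = inits, n.chains = n_chains,
                          n.adapt = n_adapt, quiet = TRUE)
  update(jm, n_warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("mu", "rho", "sigma", "b0", "b1", "b2"),
                              n.iter = n_draws, progress.bar = "none")

  par_names <- colnames(samp[[1]])
  draws <- array(NA_real_, dim = c(n_draws, n_chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(n_chains)) draws[, ch, ] <- as.matrix(samp[[ch]])

  flat <- matrix(draws, nrow = n_draws * n_chains,
                 dimnames = list(NULL, par_names))
  qs <- apply(flat, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  ess <- as.numeric(coda::effectiveSize(samp))
  summary_tbl <- tibble::tibble(
    parameter = rename_jags_params(par_names, ids),
    mean = unname(colMeans(flat)),
    sd = unname(apply(flat, 2, sd)),
    q2.5 = unname(qs[1, ]),
    q97.5 = unname(qs[2, ]),
    rhat = unname(apply(draws, 3, rhat_rank_normalized)),
    ess = ess)

  max_rhat <- max(summary_tbl$rhat, na.rm = TRUE)
  if (is.finite(max_rhat) && max_rhat > rhat_threshold) {
    warn(sprintf("convergence warning: max R-hat %.3f exceeds %.3f",
                 max_rhat, rhat_threshold))
  }

  subj_cols <- function(stub) paste0(stub, "[", seq_len(n_subj), "]")
  subject_means <- cbind(b0 = colMeans(flat[, subj_cols("b0"), drop = FALSE]),
                         b1 = colMeans(flat[, subj_cols("b1"), drop = FALSE]),
                         b2 = colMeans(flat[, subj_cols("b2"), drop = FALSE]))
  rownames(subject_means) <- ids

  group_cols <- c(paste0("mu[", 1:3, "]"), paste0("rho[", 1:3, "]"),
                  paste0("sigma[", 1:3, "]"))
  group_draws <- flat[, group_cols]
  colnames(group_draws) <- rename_jags_params(group_cols, ids)

  structure(list(summary = summary_tbl,
                 subject_ids = ids,
                 dogmatism = setNames(dog, ids),
                 subject_means = subject_means,
                 group_draws = group_draws,
                 n_chains = n_chains, n_draws = n_draws,
                 rhat_threshold = rhat_threshold,
                 max_rhat = max_rhat),
            class = "seek_posterior")
}

rename_jags_params <- function(par_names, ids) {
  out <- par_names
  for (k in 1:3) {
    out[out == sprintf("mu[%d]", k)] <- sprintf("mu_B%d", k - 1)
    out[out == sprintf("rho[%d]", k)] <- sprintf("rho%d", k - 1)
    out[out == sprintf("sigma[%d]", k)] <- sprintf("sigma_B%d", k - 1)
  }
  m <- regmatches(out, regexec("^(b[012])\\[(\\d+)\\]$", out))
  hit <- lengths(m) == 3
  out[hit] <- vapply(m[hit], function(g) {
    paste0(g[2], "_", ids[as.integer(g[3])])
  }, character(1))
  out
}

# Rank-normalized split R-hat for one parameter (draws: iterations x chains).
rhat_rank_normalized <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  n <- nrow(draws)
  half <- floor(n / 2)
  split_draws <- cbind(draws[seq_len(half), , drop = FALSE],
                       draws[(n - half + 1):n, , drop = FALSE])
  S <- length(split_draws)
  if (var(as.numeric(split_draws)) == 0) return(1)
  z <- qnorm((rank(split_draws) - 3 / 8) / (S + 1 / 4))
  z <- matrix(z, nrow = half)
  m <- ncol(z)
  chain_means <- colMeans(z)
  B <- half * var(chain_means)
  W <- mean(apply(z, 2, var))
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.seek_posterior <- function(x, ...) {
  cat("<seek_posterior>", length(x$subject_ids), "subjects,",
      x$n_chains, "chains x", x$n_draws, "draws\n")
  cat("  max R-hat:", format(x$max_rhat, digits = 4), "\n\n")
  grp <- x$summary[x$summary$parameter %in%
                     c(paste0("mu_B", 0:2), paste0("rho", 0:2),
                       paste0("sigma_B", 0:2)), ]
  print(as.data.frame(grp), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Credible-interval decision on the embedding slopes
#'
#' Extracts the 95% credible interval of each embedding slope `rho0`, `rho1`,
#' `rho2` from a fitted [fit_hierarchical()] posterior and flags a slope as
#' significant when its central interval excludes zero. Intervals are
#' treated as closed: an interval with zero exactly at an endpoint does not
#' exclude it.
#'
#' @param posterior A `seek_posterior` object.
#' @return A tibble with columns `parameter`, `mean`, `q2.5`, `q97.5`,
#'   `excludes_zero`.
#' @export
summarize_embedding <- function(posterior) {
  stopifnot(inherits(posterior, "seek_posterior"))
  rows <- posterior$summary[posterior$summary$parameter %in% paste0("rho", 0:2), ]
  tibble::tibble(parameter = rows$parameter,
                 mean = rows$mean,
                 q2.5 = rows$q2.5,
                 q97.5 = rows$q97.5,
                 excludes_zero = rows$q2.5 > 0 | rows$q97.5 < 0)
}
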
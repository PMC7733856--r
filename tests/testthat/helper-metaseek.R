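# Independent brute-force logistic evaluation (the oracle the seek model is
# checked against; deliberately written without seek_probability()).
brute_logistic <- function(b, conf, cost) {
  1 / (1 + exp(-(b[1] + b[2] * conf + b[3] * cost)))
}

brute_nll <- function(b, design) {
  total <- 0
  for (r in seq_len(nrow(design))) {
    p <- brute_logistic(b, design$confidence_encoded[r], design$cost_encoded[r])
    total <- total - log(if (design$sought[r] == 1) p else 1 - p)
  }
  total
}

# canonical encoding of the 3-level confidence (population z-score of a
# balanced 3-point variable)
enc3 <- function(level) (level - 2) / sqrt(2 / 3)

# Seek-policy design rows for one subject with known betas, bypassing the
# perceptual front end: confidence levels drawn with given frequencies,
# costs alternating low/high.
make_design <- function(betas, n_trials = 100, seed = 1,
                        conf_probs = c(0.3, 0.4, 0.3), subject_id = "s1") {
  withr::with_seed(seed, {
    lev <- sample(1:3, n_trials, replace = TRUE, prob = conf_probs)
    cost <- rep_len(c(0L, 1L), n_trials)
    conf <- enc3(lev)
    p <- 1 / (1 + exp(-(betas[1] + betas[2] * conf + betas[3] * cost)))
    tibble::tibble(subject_id = subject_id,
                   sought = rbinom(n_trials, 1, p),
                   confidence_encoded = conf,
                   cost_encoded = cost)
  })
}

# A whole cohort of seek-policy designs with dogmatism-shifted betas; the
# light-weight generator used for hierarchical recovery and calibration
# studies where the perceptual front end is irrelevant.
make_policy_cohort <- function(n_subjects, pop, n_trials = 100, seed = 1) {
  withr::with_seed(seed, {
    dog <- as.numeric(scale(rnorm(n_subjects)))
    betas <- sample_subject_params(pop, dog, seed = seed + 1)
    ids <- sprintf("p%04d", seq_len(n_subjects))
    designs <- lapply(seq_len(n_subjects), function(i) {
      make_design(betas[i, ], n_trials = n_trials, seed = seed + 1000 + i,
                  subject_id = ids[i])
    })
    list(design = dplyr::bind_rows(designs),
         dogmatism = stats::setNames(dog, ids),
         betas = betas)
  })
}

# subject-level data with a known linear mediation structure on the
# standardized scale: a = x -> m path, b = m -> y path, cp = direct path
make_mediation_data <- function(n, a, b, cp, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    m <- a * x + sqrt(max(0, 1 - a^2)) * rnorm(n)
    y <- b * m + cp * x + sqrt(max(0.05, 1 - b^2 - cp^2)) * rnorm(n)
    data.frame(x = x, m = m, y = y)
  })
}
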
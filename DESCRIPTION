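Package: metaseek
Title: Simulation and Hierarchical Modelling of Uncertainty-Guided
    Information Seeking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying metacognitive control of information search
    in costed perceptual decision tasks. Provides a generative simulator of a
    two-alternative dot-discrimination task with confidence ratings, adaptive
    staircase calibration, and costed post-decision information seeking; a
    trial-by-trial logistic model of the seek decision fitted per subject or
    hierarchically with an individual-difference covariate (dogmatism)
    embedded in the group-level priors via MCMC; subject-level standardized
    regressions with delta R-squared, polynomial factor-relationship fits
    selected by BIC, sample pooling for internal meta-analysis; and a
    quasi-Bayesian Monte Carlo mediation analysis. Includes CSV table schemas
    and a reproducible staged analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    rjags,
    coda,
    jsonlite,
    yaml,
    withr,
    tibble,
    dplyr,
    readr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
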
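Package: phenogp
Title: Gaussian-Process Functional ANOVA for Microbial Growth Phenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric Bayesian analysis of plate-reader growth curves.
    Fits a Gaussian-process functional analysis of variance (GP FANOVA) to
    log-scale optical-density time series, decomposing growth into latent
    functional effects of strain, condition, their interaction, and batch,
    with sum-to-zero identifiability enforced through an orthonormal contrast
    parameterization. Posterior inference uses Gibbs updates for the latent
    functions and slice sampling for kernel hyperparameters. From the
    posterior it derives the OD-delta functional difference between a mutant
    and its parent strain, its summed-square magnitude used to rank phenotype
    severity, credible-interval significance calls, a universal magnitude
    cutoff, hierarchical clustering of phenotype trajectories, correlation
    enrichment and hypergeometric gene-set overlap tests, and a bipartite
    strain-condition phenotype network. A synthetic-data generator simulates
    growth cohorts from the model's own generative structure for testing and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
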
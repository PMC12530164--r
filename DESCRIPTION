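Package: csddm
Title: Hierarchical Bayesian Drift Diffusion Modelling for Ambulatory
    Change-Detection Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing response time and accuracy data from
    smartphone-administered visual working memory change-detection tasks
    (the Color Shapes paradigm) with a hierarchical Bayesian drift
    diffusion model. Provides an exact two-boundary Wiener first-passage
    likelihood, a synthetic-cohort simulator reproducing the 2x2x2x2
    factorial session structure with missingness and contaminant response
    times, trial-retention preprocessing with engagement and accuracy
    summaries, multilevel model fitting by adaptive
    Metropolis-within-Gibbs with person-by-condition parameters on
    transformed scales, posterior contrasts for the task manipulations,
    posterior predictive checks on response-time quantiles, and Bayesian
    Pearson correlations with Bayes factors for parameter-covariate
    associations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
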
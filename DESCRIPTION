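Package: multistep
Title: Multistep (Armitage-Doll) Models of Age-Specific Disease Incidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether the age-specific incidence of a
    disease is consistent with a multistep (Armitage-Doll) pathogenic
    process.  Provides a validated data model for age-sex incidence tables
    with credible intervals, the log-log transform with measurement
    uncertainty, a stochastic multistep cohort simulator (sequential or
    any-order steps, subpopulation mixtures, sex-specific exposure
    multipliers, susceptible fractions, extinction, and rare-event
    importance sampling), Bayesian fits of the power-law, broken-stick,
    sex-stratified, beta-extinction and susceptibility incidence models via
    an adaptive-Metropolis sampler, bridge-sampling marginal likelihoods
    with Bayes-factor model comparison, Bayesian R-squared, and an
    end-to-end analysis pipeline with report tables and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    coda,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    rjags,
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
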
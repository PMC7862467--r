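Package: cogedkit
Title: Simulation and Bayesian Analysis of Cross-Domain Cognitive Effort
    Discounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for simulating the Cognitive Effort Discounting (COG-ED)
    paradigm across working-memory (N-back) and speech-in-noise domains and
    for running the associated Bayesian correlation analysis end to end.
    Provides latent-trait cohort simulation with a configurable domain-general
    motivation factor, the adaptive halving staircase used to titrate offers
    to an indifference point, subjective-value scoring on the 0-2 scale,
    z-score composites and covariate residualization, Bayes factors with
    posterior summaries for (partial) Pearson correlations under
    truncated-Cauchy or stretched-beta priors, and sequential Bayes Factor
    Design Analysis of evidence-based stopping rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
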
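Package: msomaug
Title: Multispecies Occupancy Models with Data Augmentation for Insect
    Pollinator Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits hierarchical Bayesian multispecies occupancy models (MSOMs)
    with data augmentation to detection/non-detection surveys of insect
    pollinator communities on flowering plants. Species-specific occupancy and
    detection probabilities are modelled as random effects drawn from
    community-level distributions, and all-zero detection histories are
    appended so that the number of completely undetected taxa can be
    estimated. Includes a Metropolis-within-Gibbs sampler with closed-form
    updates for the binary latent states, credible-interval based covariate
    screening and forward selection, deviance-based posterior predictive
    checks (Bayesian p-values), derived species-richness summaries, an exact
    enumeration oracle for small instances, and a synthetic-data generator
    replicating a two-plant, spatially replicated garden survey design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    coda,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
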
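Package: fevertreat
Title: Bayesian Item Response Models of Fever Treatment-Seeking Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian hierarchical three-parameter logistic (3PL) item
    response models to household-survey records of formal-sector fever
    treatment for febrile children, with the latent treatment-seeking trait
    regressed on travel time to the nearest health facility. Provides a
    DHS-style two-stage cluster-survey simulator with known ground-truth
    parameters, an adaptive Metropolis-within-Gibbs sampler for four model
    variants (fixed effects, truncated difficulty prior, random intercepts,
    correlated random slopes and intercepts with a Wishart precision prior),
    Gelman-Rubin and Raftery-Lewis convergence diagnostics, DIC model
    comparison, hold-out ROC validation, and regional probability summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    coda,
    pROC,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
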
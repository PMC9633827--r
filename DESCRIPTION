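Package: moralddm
Title: Hierarchical Drift-Diffusion Modelling of Moral Cost-Benefit Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how people trade off money against harm in
    two-alternative forced-choice tasks where each option couples an amount of
    money with a number of painful electric shocks. Provides an
    indifference-point trial generator for harm-averse agents, a multi-attribute
    drift-diffusion model (DDM) with attribute-dependent drift, a Wiener
    first-passage-time likelihood, hierarchical Bayesian estimation over
    subjects and conditions by MCMC, formal model comparison (DIC,
    posterior-predictive mean squared error, Gelman-Rubin diagnostics),
    model-free behavioural summaries, a linear mixed-effects model of
    third-party blame judgments, and the linkage between fitted drift weights
    ("temptation") and blame gaps. Includes synthetic-study generators with
    ground-truth manifests for parameter- and model-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    grDevices,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
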
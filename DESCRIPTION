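Package: glopr
Title: Global-Local Objective Pursuit Models of Approach-Avoidance Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generative modeling of two-agent approach-avoidance movement on a
    screen with the global-local objective pursuit (GLOP) model, simulation of
    dyadic trials against scripted opponent profiles, amortized neural
    estimation of the model's latent parameters from partial trajectories
    (gated recurrent network with Monte-Carlo-dropout posteriors), real-time
    classification of a player's latent goal (Attack, Avoid, Inspect), and
    evaluation tools for parameter recovery and resynchronized posterior
    predictive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
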
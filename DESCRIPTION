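Package: ktom
Title: Recursive Theory-of-Mind Agents and Bayesian Model Selection for
    Repeated Dyadic Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits learning agents for repeated 2x2 games such
    as hide-and-seek (matching pennies). Implements recursive meta-Bayesian
    theory-of-mind (k-ToM) learners together with a comparison set of
    non-mentalizing and non-Bayesian models (hierarchical Gaussian filter,
    Bayesian sequence learners, influence models, reinforcement learning,
    win-stay/lose-switch, Nash and biased-random policies). Provides a
    seeded dyadic game arena and synthetic-cohort generator, Volterra
    (lagged logistic) decomposition of binary choice sequences, per-session
    Laplace approximations to the Bayesian model evidence, and group-level
    random-effects Bayesian model selection with family-level inference and
    between-condition model-identity tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
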
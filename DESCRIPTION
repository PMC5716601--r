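Package: valuelicit
Title: Comparing Economic Value Functions Elicited by Choice, Rating and
    Effort Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating subjective value functions of composite
    monetary outcomes (a gain for oneself and a donation to a charity) from
    three elicitation paradigms: binary choice, desirability rating and
    grip-force production. Provides a twelve-member space of candidate value
    functions (including the constant elasticity of substitution family),
    task-specific observation models (softmax choice, linearly scaled
    ratings and forces), maximum a posteriori fitting with a Laplace
    approximation to the model evidence, random-effects group-level Bayesian
    model selection with family-wise inference, parameter-sharing model
    comparison across tasks, A-optimal adaptive design of choice offers, a
    convergence analysis of estimation efficiency, and a synthetic-cohort
    simulator reproducing the three-task experimental design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
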
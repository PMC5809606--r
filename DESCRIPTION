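Package: leukdyn
Title: Feedback-Regulated Models of Leukemic and Healthy Hematopoiesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation models of acute myeloid leukemia
    in which leukemic cells either depend on endogenous hematopoietic
    cytokines for expansion (cytokine-dependent AML) or expand autonomously
    and are limited only by bone-marrow crowding (cytokine-independent AML).
    Provides trajectory simulation with event detection, expansion-time
    scans over leukemic self-renewal, simulation of exogenous cytokine
    stimulation with outcome classification by effective growth rates,
    bounded multistart least-squares calibration of both models to sparse
    marrow-blast time courses with an RMSE-based model-selection rule,
    a synthetic relapse-cohort generator, and Kaplan-Meier / log-rank
    survival comparison of the resulting patient groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    lhs,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
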
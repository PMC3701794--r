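Package: ssysnet
Title: S-System Network Inference from Metabolite Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers interactive network models of metabolite time courses in the
    S-system power-law formalism. Provides forward integration of S-system
    differential equations with a compiled right-hand side, parameter estimation
    by a real-coded genetic algorithm (UNDX crossover under a minimal-generation-gap
    alternation scheme) minimizing the average relative error per sampling point,
    perturbation-based sensitivity ranking of interrelated coefficients,
    edge-by-edge comparison of fitted networks across experimental conditions with
    sign-reversal detection, correlation-based variable selection, and a seeded
    synthetic-data generator for end-to-end validation. Ships the fitted
    five-amino-acid plasma network parameter sets for healthy and hyperglycemic
    mice as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    igraph,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
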
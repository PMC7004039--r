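Package: firedyn
Title: Stochastic Fire-Vegetation Dynamics of Mediterranean Plant Communities
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates the successional dynamics of the six dominant plant types of
    Western Mediterranean ecosystems (evergreen oaks, Aleppo pine, Rosmarinus, Ulex,
    Cistus and the perennial grass Brachypodium retusum) under a hierarchical
    competition-colonization model coupled to a stochastic, cover-dependent fire
    regime with differential seeder and resprouter post-fire responses and seed-bank
    dynamics. Provides closed-form no-fire equilibria, a compiled fixed-step
    Runge-Kutta integrator with instantaneous fire events, factorial aridity-scenario
    experiments at long (millennia) and short (century) timescales, a simulated
    annealing calibration against old-field chronosequence and experimental fire-plot
    cover data, Monte Carlo uncertainty envelopes, and a synthetic observation
    generator for fully reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
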
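Package: mswb
Title: Modelling Momentary Subjective Well-Being in Social Risky-Choice Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and model-based analysis of momentary subjective
    well-being (happiness) in risky-choice tasks with a social partner.
    Provides generators for non-social and social session schedules, a
    prospect-theory partner agent, exponential-decay happiness models
    (non-social, simple-inequality, and guilt-envy variants), per-subject
    nonlinear least-squares fitting with BIC model comparison, model-free
    descriptive analyses of inequality contexts, linkage of guilt/envy
    reactivity to dictator-game generosity, and a fully reproducible
    synthetic-cohort generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
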
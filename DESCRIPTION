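Package: icudose
Title: Model-Informed Precision Dosing of Antibiotics in Critical Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-informed precision dosing (MIPD) of antibiotics
    in intensive-care patients: a registry of published population
    pharmacokinetic models with covariate equations, a fixed-step
    Runge-Kutta ODE simulator for one- and two-compartment models with
    infusion schedules, maintenance- and loading-dose calculators built on
    PK linearity and superposition, a clinical dosing-advice algorithm with
    safety constraints and warnings, Bayesian maximum a posteriori
    individualization from measured plasma concentrations via simulated
    annealing, and a synthetic ICU cohort generator for end-to-end regimen
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
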
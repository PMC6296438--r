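Package: circuitweaver
Title: Aspect-Oriented Design and Model Generation for Synthetic Gene Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design synthetic gene circuits from typed genetic parts and weave
    them with aspects: point cuts select join points in the compiled execution
    flow of a circuit, advice injects or replaces parts, and type advice
    attaches properties used to generate mathematical models. Generates
    reaction-network models under mass-action and Shea-Ackers kinetic
    strategies with stoichiometry, plain-text, CSV and SBML output; generates
    agent/site rule-based models in a Kappa dialect for stochastic simulation;
    transforms models with cross-cutting context aspects (exponential,
    logistic and lag-logistic host growth; shared-protease post-translational
    coupling); and simulates the results deterministically (stiff ODE
    integration) or stochastically (Gillespie direct method), with detectors
    for oscillation and switchable-oscillator behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    lhs,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
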
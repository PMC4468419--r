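Package: dualproc
Title: Evolutionary Dynamics of Automatic and Controlled Resource Consumption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agent-based eco-evolutionary simulator for populations of
    dual-process consumers. Each agent carries a heritable propensity C to
    override a fast automatic consumption habit with slower controlled
    deliberation. Controlled acts solve an intertemporal consume-versus-store
    problem by stochastic dynamic programming, but lose direct contests over
    resources to automatic acts. Fitness (lifetime mean energy) is
    precomputed on a lookup grid and drives Wright-Fisher evolution of C,
    optionally coupled to the environment through fitness-driven population
    growth or control-driven environmental enrichment, which produce
    boom-bust trajectories and limit cycles in the prevalence of control.
    Includes trajectory diagnostics (equilibrium summaries, limit-cycle
    detection) and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
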
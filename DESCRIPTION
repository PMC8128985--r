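Package: netkin
Title: Network-Structured Kinetic Models of Interacting Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation and mean-field analysis of network-structured
    kinetic models of social interactions. Provides an exact Gillespie simulator
    for N-agent systems with asymmetric (active/passive) pairwise interactions on
    a weighted spatial network, Vlasov (drift) approximations solved by
    characteristics, monokinetic closures, and three model instantiations:
    dialect evolution on the memory simplex, social-norm construction on discrete
    node networks, and a nonlocal SIR epidemic model with its reaction-diffusion
    rewriting and local limits. Includes interaction-kernel discretization,
    nonlocal Laplacians, concentration and conservation diagnostics, and
    configuration-driven reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
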
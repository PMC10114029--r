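Package: culturesim
Title: Agent-Based Simulation of Cultural Repertoire Dynamics in
    Connected Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-time, agent-based simulation of the accumulation and
    loss of cultural tools in one or more populations connected by rare
    migration. Tools are invented at a per-individual rate, establish with a
    probability equal to an exponentially distributed selection coefficient,
    and are lost at a rate inversely proportional to population size.
    Migrants carry a fraction (or fixed number) of their source population's
    repertoire to a neighbouring population, where each carried tool
    establishes with its original selection coefficient. The package
    provides the simulator, a closed-form layer (equilibrium repertoire
    size, effective cultural population size, cultural-rescue arithmetic),
    config-driven experiment drivers (connectivity heat maps, unique-tool
    counts, rescue and connectivity-curve scans, accumulation timelines),
    and delimited-text input/output with a thin command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
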
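Package: formosemap
Title: Free-Energy Maps and Microkinetics for the Formose Reaction with Bisulfite
Version: 0.1.0
Authors@R: person("Formosemap", "Maintainers", email = "maintainers@formosemap.dev",
    role = c("aut", "cre"))
Description: Tools for assembling aqueous-solution free energies of small CHOS
    molecules from quantum-chemistry components, placing them on a common
    reference scale (relative free energies of formation against CO2, H2, H2O
    and H2SO3), and analysing the resulting reaction network of the formose
    system in the presence of SO2/bisulfite. Includes reaction free energies
    and activation barriers, Hess-cycle consistency audits, Boltzmann
    speciation of isomer and adduct groups, Eyring-rate mass-action kinetics
    with a built-in stiff integrator, autocatalysis and Cannizzaro-leakage
    metrics, a thermodynamically consistent synthetic-data generator with
    controlled inconsistency injection, and a packaged free-energy map of the
    bisulfite formose network with per-value provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
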
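Package: dhaflux
Title: Kinetic and Constraint-Based Modeling of DHA Production in
    Crypthecodinium cohnii
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing docosahexaenoic acid (DHA) production
    potential in the heterotrophic dinoflagellate Crypthecodinium cohnii
    grown on glucose, glycerol or ethanol.  The package couples a
    pathway-scale kinetic ODE model of substrate uptake and central carbon
    metabolism with a reduced medium-scale constraint-based stoichiometric
    model carrying a biomass equation and a DHA overproduction sink.  It
    provides steady-state simulation and parameter estimation for the
    kinetic model under metabolite concentration caps, flux balance
    analysis with parsimonious canonicalisation, feasibility validation of
    kinetic steady-state flux sets inside the stoichiometric model,
    growth- and uptake-rate estimation from batch cultivation curves, and
    the carbon-accounting metrics (C1 uptake, carbon per gram biomass,
    carbon routed to Acetyl-CoA and DHA) used to compare substrates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
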
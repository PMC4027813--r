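Package: ccmsim
Title: Steady-State Reaction-Diffusion Model of the Cyanobacterial
    CO2-Concentrating Mechanism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Solves the coupled steady-state reaction-diffusion problem for
    CO2 and bicarbonate in a spherical cyanobacterial cell containing a
    central enzyme-filled microcompartment (carboxysome). Includes reversible
    Michaelis-Menten carbonic anhydrase kinetics, competitive RuBisCO
    carboxylation/oxygenation, active bicarbonate transport and facilitated
    CO2 uptake at the cell membrane, and a non-selective permeable
    carboxysome shell. Provides a conservative finite-volume nonlinear
    solver, closed-form solutions in the linearizable kinetic regimes,
    membrane flux budgets, (jc, kc) phase-space scans with iso-concentration
    contours, uptake-partition analysis, and comparisons of cellular enzyme
    organization strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
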
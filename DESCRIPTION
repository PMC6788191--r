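Package: liabgame
Title: Evolutionary Game Dynamics of School Sports Injury Liability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing liability rules for school sports injury
    accidents as an asymmetric two-population evolutionary game between a
    school and the students and their guardians. Builds the 2x2 payoff
    bimatrix implied by strict or proportional liability, derives the
    replicator dynamics in closed form, enumerates rest points including the
    interior equilibrium, classifies local stability (evolutionarily stable
    strategies) from the Jacobian determinant and trace, integrates
    trajectories numerically, and reproduces scenario sweeps over the
    liability-share parameters with phase-portrait and basin reporting.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
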
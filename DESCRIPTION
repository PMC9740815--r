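Package: hapthermal
Title: Molecular Dynamics of Hydroxyapatite Thermal Dehydroxylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds hexagonal hydroxyapatite (HAP) supercells from printed
    lattice parameters, runs all-atom molecular dynamics with a collisional
    (stochastic elastic-collision) thermostat under fixed-temperature and
    linear-heating protocols, counts hydroxyl (OH) ion detachment events
    along trajectories with a permanent per-ion ledger, detects melting via
    radius-of-gyration collapse, and computes OH-removal energy profiles
    together with the associated dispersion and uncertainty arithmetic.
    Includes a config-driven Coulomb plus 6-12/9-6 Lennard-Jones force field,
    extended-XYZ and PDB readers/writers, and synthetic fixture generators
    (toy ionic crystals, scripted trajectories, Maxwell velocity ensembles)
    so the whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
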
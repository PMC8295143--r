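Package: ireplan
Title: Electro-Thermal Simulation and Protocol Optimization for Irreversible Electroporation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treatment-planning toolkit for irreversible electroporation (IRE)
    with two parallel needle electrodes. Solves the quasi-static electric-field
    problem with field-dependent tissue conductivity (Picard iteration on a
    structured finite-volume grid) coupled to the Pennes bioheat equation with
    duty-cycle-averaged Joule heating, extracts ablation area and peak
    temperature responses, and drives a Taguchi L18 screening / quadratic
    response-surface / desirability-optimization pipeline that finds the
    protocol maximizing the ablation area while keeping tissue below the
    50 degree Celsius thermal-damage threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
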
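Package: enzymn
Title: Toy Multiscale Modelling of Enzyme-Manganese Synergistic Catalysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale models of enzyme-metal hybrid catalysis: Gaussian-smoothed
    metal coordination numbers and screened charge polarization for Mn-O
    coordination shells, a toy molecular-mechanics force field with analytic
    forces, position-Verlet dynamics with Berendsen-type temperature and
    pressure coupling, climbing-image nudged-elastic-band transition-state
    search with finite-difference Hessian validation, umbrella sampling with
    WHAM unbiasing to potentials of mean force, geometric hydrogen-bond
    analysis, and the activation-energy reduction, synergy-decomposition and
    error statistics used to summarise quinazolinone synthesis over the
    QD-01..QD-15 substrate series. Synthetic-data generators plant known
    coordination shells, reaction surfaces with analytic saddles, hydrogen-bond
    occupancies and substrate activation-energy series so every stage can be
    scored against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
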
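Package: odoxpk
Title: Population Pharmacokinetics and Dose-Feasibility Simulation for
    Oral Docetaxel plus Encequidar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint population pharmacokinetic modelling of total and unbound
    plasma docetaxel after intravenous docetaxel and oral docetaxel given with
    encequidar, and a simulation-based dose-feasibility framework built on it.
    Provides an exact (eigendecomposition) solver for three-compartment linear
    disposition with first-order lagged absorption on the unbound scale,
    log-normal between-subject variability, a combined additive/proportional
    residual model with within-sample correlation between total and unbound
    observations, M6 handling of below-quantification data, Laplace
    marginal-likelihood estimation, a synthetic phase-I trial generator,
    exposure metrics including the area under the curve over an effective
    concentration (AUCOEC), probability-of-target-attainment (PTA) grids with a
    paired virtual-patient design, and GO / CONDITIONAL GO / NO-GO
    classification of candidate oral regimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
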
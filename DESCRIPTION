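Package: posapk
Title: Population Pharmacokinetics and Dose Simulation for Posaconazole
    Tablets in Children with Cystic Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pharmacometrics pipeline for sparse therapeutic-drug-monitoring
    (TDM) data on posaconazole gastroresistant tablets in children with cystic
    fibrosis. Implements a one-compartment first-order absorption/elimination
    model with fixed allometric weight scaling, nonlinear mixed-effects
    estimation by first-order conditional estimation with interaction (FOCE-I)
    backed by an adaptive Gauss-Hermite quadrature oracle, stepwise covariate
    model building on clearance, model diagnostics (conditional weighted
    residuals, visual predictive checks, nonparametric bootstrap), and a Monte
    Carlo dose-simulation engine computing probability of target attainment
    for steady-state trough and AUC targets. A synthetic-study generator
    reproduces the sparse TDM design so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite
Config/testthat/edition: 3
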
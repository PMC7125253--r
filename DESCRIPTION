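Package: fupkpd
Title: Population Pharmacokinetic-Pharmacodynamic Modelling of
    Continuous-Infusion 5-Fluorouracil Myelosuppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation tools for a semi-physiological
    pharmacokinetic-pharmacodynamic model of 5-fluorouracil (5FU) given as
    continuous venous infusion: a two-compartment parent model with linear
    elimination coupled to a one-compartment 5-fluoro-5,6-dihydrouracil
    (5FUH2) metabolite model, driving a transit-compartment (Friberg-type)
    model of drug-induced leukopenia. Includes an analytic piecewise
    pharmacokinetic solver, an adaptive pharmacodynamic integrator, a
    synthetic study generator emulating a 30-subject continuous-infusion
    trial, a native first-order conditional estimation with interaction
    (FOCE-I) engine for nonlinear mixed-effects fitting, likelihood-ratio
    covariate testing, nonparametric bootstrap, visual predictive checks and
    dosing-scenario simulation (monotherapy vs cisplatin combination;
    FOLFIRINOX vs de Gramont 5FU components).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
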
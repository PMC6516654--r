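Package: vanchd
Title: Population Pharmacokinetics and Dosing of Vancomycin in
    Intermittent Hemodialysis and Hemodiafiltration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-compartment pharmacokinetic simulation of vancomycin in
    patients on intermittent online hemodiafiltration or low-flux
    hemodialysis, with a switchable extracorporeal clearance term
    (CL = CLm + fr*CLcr + Qec*Eec) that is active only during dialysis
    sessions.  Provides lean-body-mass covariate scaling of the
    distribution volumes, a concentration-dependent assay-error model,
    iterative two-stage Bayesian (ITSB) population estimation with an
    AIC-guided stepwise parameter-setting search, eta-shrinkage and
    bootstrap diagnostics, external predictive-performance evaluation
    (MDPE/MDAPE with bootstrap confidence intervals, weighted residuals),
    a worst-case-window AUC24h dosing-regimen optimizer that generates
    loading/maintenance dose tables for dialysis schedules, and a seeded
    synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
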
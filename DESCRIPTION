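Package: pkarisk
Title: Population Pharmacokinetics and Biomarker-Based Acute Rejection
    Risk Modelling in Kidney Transplantation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequential population pharmacokinetic and pharmacodynamic
    modelling of immunosuppressant exposure and urinary biomarkers in
    adult kidney transplant recipients. Implements a two-compartment
    oral-absorption model with lag time and allometric scaling, a
    deterministic Laplace-type approximate marginal likelihood for
    nonlinear mixed-effects estimation with empirical Bayes estimates
    and shrinkage, stepwise covariate selection, cumulative-exposure
    metrics, a visit-level logistic regression linking miR155-5p
    urinary expression and drug exposure to the probability of acute
    rejection, model-evaluation machinery (prediction-corrected and
    categorical visual predictive checks, normalized prediction
    distribution errors, nonparametric bootstrap), and a synthetic
    multicentre-trial generator for design-based simulation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), deSolve, jsonlite, optparse, knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
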
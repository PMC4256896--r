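Package: vancoci
Title: Population Pharmacokinetics of Continuous-Infusion Vancomycin in
    ECMO and CRRT Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonlinear mixed-effects analysis of continuous-infusion
    vancomycin in critically ill patients on extracorporeal membrane
    oxygenation (ECMO) and matched controls.  Implements a two-compartment
    model with zero-order infusion input solved in closed form, Laplace and
    FOCE-I approximations to the marginal likelihood, forward stepwise
    covariate screening on the objective-function value, nonparametric
    subject-level bootstrap confidence intervals, Monte Carlo probability of
    target attainment for loading/maintenance dose regimens against a 20
    mg/L target, the clinical dosing calculators of the originating ICU
    protocol (creatinine-clearance banded continuous-infusion doses, CRRT
    intensity, concentration classification and dose adjustment, matched
    control selection), and a seeded synthetic-cohort generator that
    emulates the study design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
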
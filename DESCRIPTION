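Package: picuree
Title: Resting Energy Expenditure Prediction for Critically Ill Children
Version: 0.1.0
Authors@R:
    person("PICU", "Modelling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating resting energy expenditure (REE) in
    pediatric intensive care. Processes indirect-calorimetry gas-exchange
    series (steady-state detection, respiratory-quotient filtering, the
    modified Weir equation), evaluates classical predictive equations
    (Harris-Benedict, Schofield, Oxford, FAO/WHO/UNU, Talbot tables, the
    VCO2-based Mehta equation) from a versioned coefficient registry,
    computes LMS-based growth z-scores and WHO nutritional-status classes,
    and fits small neural-network regressors whose inputs are chosen by a
    genetic algorithm that jointly selects variables and a
    distribution-matched train/test split. A synthetic-cohort generator
    with known ground truth makes the whole pipeline testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
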
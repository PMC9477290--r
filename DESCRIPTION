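Package: ticsim
Title: Dynamic Microsimulation of TICS27 Cognitive Trajectories and Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for projecting cognitive function in older adults with a
    dynamic microsimulation built around the 27-point Telephone Interview for
    Cognitive Status score (TICS27). Provides maximum-likelihood ordered
    probit and probit fitters for the biennial TICS27 and mortality transition
    models (piecewise-linear age and log-BMI splines, lagged scores, verified
    cognitive status), a verified-status state machine with absorbing
    dementia/MCI classification, a Monte Carlo projection engine over two-year
    steps, a synthetic survey-like cohort generator with missing-not-at-random
    proxy missingness, sequential-regression multiple imputation with
    predictive mean matching, and a validation suite (k-fold cross-validated
    simulation, weighted score-distribution comparison, cognitive/mortality
    transition matrices, and replicate-fraction ROC/AUROC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), MASS, pROC, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
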
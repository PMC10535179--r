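Package: nanomill
Title: Breakage Kinetics, Microhydrodynamics, and Process Economics of Wet
    Stirred Media Milling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing wet stirred media milling (WSMM) of drug
    nanosuspensions. Fits the nth-order breakage kinetics model to median
    particle-size time series, solves the microhydrodynamic granular-
    temperature balance for bead-collision parameters, predicts kinetics
    parameters for unseen runs with elastic-net and decision-tree models
    under a leave-one-out/test-RMSE selection protocol, and ranks process
    conditions with merit scores and a bead wear/capital-cost model. A
    synthetic-study generator emulates a full-factorial milling campaign
    (noisy size time series, power and viscosity responses, intermittent
    thermal cycling) so every stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    readr,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
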
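Package: spermophagy
Title: Penalized Logistic Modelling of Sperm Phagocytosis by Neutrophils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the dose-dependent regulation of in vitro
    sperm phagocytosis (spermophagy) by polymorphonuclear neutrophils in
    response to bovine oviductal fluid components (BSA, LH, BOEC co-culture,
    angiotensin II, prostaglandin E2, alpha-1 acid glycoprotein and
    endothelin-1).  Implements a ridge-penalized quasi-likelihood logistic
    model calibrated by an iterative gradient-ascent procedure with a
    dynamically adapted step size, the lambda-grid penalty scan, model
    comparison statistics (RMSE, MAE, Nash-Sutcliffe efficiency, Willmott's
    index of agreement, AIC), the Murtaugh delta-AIC variable-removal test,
    marginal dose effects, and prediction and classification of single and
    combined component effects.  A multi-study synthetic data generator and
    a bundled 15-row literature validation table support end-to-end testing
    without external data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
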
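Package: ltfucorrect
Title: Correcting Programme-Level Mortality for Loss to Follow-Up in ART Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Corrects programme-level mortality estimates in antiretroviral
    therapy (ART) cohorts for deaths among patients lost to follow-up (LTFU).
    Implements the nomogram correction factor C = (1 - r) + r * (M_L / M_NL),
    a published logistic meta-regression that predicts mortality among
    patients lost from the programme's LTFU proportion, Monte-Carlo
    propagation of uncertainty in the inputs into confidence intervals for
    corrected mortality, Kaplan-Meier processing of patient-level cohort
    records under the nine-month LTFU rule, nomogram and prediction-curve
    graphics, and a synthetic-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
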
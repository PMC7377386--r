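Package: sepsisnnt
Title: Sepsis Risk After Primary-Care Infection Consultations and the
    Antibiotic Number Needed to Treat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic estimation of the probability of sepsis within
    30 days of a primary-care consultation for a common infection (respiratory
    tract, skin, or urinary tract), with and without a same-day antibiotic
    prescription, and of the number of antibiotic prescriptions needed to
    prevent one sepsis event (NNT).  A Bayesian decision tree combines five
    stratum-level input probabilities; 95% uncertainty intervals are obtained
    by probabilistic sensitivity analysis with beta-posterior draws on the
    underlying counts.  Includes a synthetic electronic-health-record cohort
    generator with known ground truth, incident-event ascertainment with
    look-back exposure linkage, a 36-deficit electronic frailty index, and the
    stratified random-sample design used to estimate consultation and
    prescribing rates.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
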
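Package: chdprev
Title: Integrative Estimation and Projection of the Congenital Heart Disease Population
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Joint estimation of time-specific birth prevalence and
    age/time-specific excess mortality of congenital heart disease (CHD)
    from survey-prevalence and cause-of-death data, using a one-compartment
    cohort model solved along characteristics, an offset log-normal data
    likelihood, and second-order smoothing priors fitted by penalized
    maximum a posteriori estimation. Includes ICD-8/9/10 multiple-cause
    death tabulation, parametric-bootstrap uncertainty intervals,
    constant-rate projection of the prevalent adult population, and a
    synthetic-data generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
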
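Package: dyadrisk
Title: Social-Context Effects on Risk Preferences in Friend Dyads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for computational analysis of risky decision making in
    age-matched friend dyads. Implements expected-utility and social-weighted
    expected-utility choice models fit per participant by maximum likelihood,
    model-based exclusion rules derived from the identifiability of the lottery
    choice set, model-free behavioral measures (proportion risky, simulated
    earnings), parameter-recovery and model-comparison harnesses, and nonlinear
    age-trend inference via penalized-spline smooths with first-derivative and
    difference-of-smooths simultaneous confidence bands. A seeded synthetic
    dyad-cohort generator reproduces the statistical structure of the study
    design so the full pipeline can be exercised without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    mgcv,
    MASS,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
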
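Package: sicklesim
Title: Individual-Based Microsimulation and Cost-Effectiveness Analysis for
    Sickle Cell Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based state-transition microsimulation of sickle
    cell disease natural history under Common Care (no treatment, hydroxyurea,
    or transfusion) and curative strategies (hematopoietic stem cell
    transplant, gene therapy). Health is tracked along four parallel
    dimensions: chronic pain, acute events, chronic disorders, and treatment
    complications, covering 26 disease attributes. The package generates
    synthetic administrative-claims populations, derives annual person-year
    panels with claims-style persistence semantics, fits penalized-regression
    prediction indices for transitions, treatment use, complications, and
    utilization, calibrates incidence intercepts to published lifetime
    prevalence targets, and performs societal-perspective cost-effectiveness
    analysis (QALYs, ICERs, probabilistic sensitivity analysis and
    cost-effectiveness acceptability curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
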
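Package: deapanel
Title: Hybrid Data Envelopment and Panel-Data Efficiency Analysis for
    Community Health Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Evaluates the allocation efficiency of community health
    resources by chaining an input-oriented data envelopment analysis
    (DEA) stage with a Cobb-Douglas panel-data production stage.  The DEA
    stage solves the CCR and BCC envelopment programs with two-phase
    slack maximisation, classifies units, projects them onto the
    efficient frontier, measures returns to scale, computes benevolent
    cross-efficiency scores, and decomposes productivity change over time
    with the Malmquist index.  The panel stage fits pooled,
    fixed-intercept, fixed-coefficient and random-effects forms of a
    log-linear Cobb-Douglas production function and runs the usual
    specification battery (Hausman test, poolability F tests, panel
    unit-root tests).  A seeded synthetic panel generator emulating a
    three-zone system of community health centers makes the whole
    pipeline runnable and testable without access to administrative data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
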
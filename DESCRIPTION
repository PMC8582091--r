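Package: cfrs
Title: Continuous Fall Risk Score for Community-Dwelling Older Adults
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and evaluates a continuous fall risk score (cFRs) for
    older adults: per-component standardized residuals from regressions on
    age and sex are summed, with protective components (cognition, physical
    function, balance, affordance perception, gait, physical activity)
    sign-flipped so that higher scores mean higher risk. Includes a cohort
    data model with validation and CSV input/output, a synthetic two-group
    cohort generator for occasional and recurrent fallers, fully
    conditional specification multiple imputation of missing components,
    group-comparison statistics (Student's t, Pearson chi-square, Cohen's d
    with magnitude bands, one-way ANOVA with Tukey post hoc, sample-size
    planning), and ROC machinery (trapezoid and Mann-Whitney AUC,
    Hanley-McNeil intervals, Youden-optimal cutoffs, Wilson and bootstrap
    intervals for classification accuracy), plus an end-to-end pipeline
    with reproducible manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
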
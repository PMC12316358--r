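Package: sletrends
Title: Register-Based Temporal Trends in Glucocorticoid and
    Hydroxychloroquine Treatment After Incident SLE
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for register-based pharmacoepidemiology of systemic
    lupus erythematosus (SLE).  Simulates synthetic population, care-visit
    and drug-dispensation registers with known ground-truth calendar-time
    treatment trends; constructs incident adult SLE cohorts with washout,
    residency, age and follow-up filters; derives dispensation-based
    exposure measures (yearly any-use flags, cumulative
    prednisolone-equivalent glucocorticoid dose, hydroxychloroquine
    coverage intervals and proportion of days covered, treatment
    combination states); and estimates temporal trends with logistic
    regression, Wilcoxon rank-sum tests and quantile regression across a
    percentile grid with person-level bootstrap confidence intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
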
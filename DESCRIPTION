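Package: cocult
Title: Population Dynamics of Pairwise Microbial Cocultures from Plate-Reader Growth Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pairwise microbial coculture experiments monitored
    by microplate optical density and end-point flow cytometry. Fits logistic
    growth models to OD600 time series and extracts latency, intrinsic growth
    rate, maximum OD and model-based area under the curve; computes a
    monoculture-referenced interaction index and classifies each coculture
    outcome as neutral, overyielding, underyielding or intermediate via
    Welch t-tests; quantifies species and strain-within-species effects with
    a nested ANOVA and compact letter displays; clusters strain-by-strain
    interaction matrices (Euclidean distance, complete linkage) and scores
    cluster stability with bootstrap and subset Jaccard resampling; and
    converts cytometry gate counts to relative-abundance fold changes. A
    generalized Lotka-Volterra simulator generates complete in-silico study
    designs with planted interaction structure for calibration and validation.
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
    minpack.lm,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    lme4,
    lmerTest,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
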
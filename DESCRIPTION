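Package: enzlim
Title: Ecoenzymatic Stoichiometry and Microbial Metabolic Limitation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vector analysis of extracellular enzyme stoichiometry for
    inferring microbial carbon, nitrogen and phosphorus limitation in
    sediments, together with the surrounding survey workflow: pooling of
    carbon-, nitrogen- and phosphorus-acquiring enzyme activities,
    vector length and angle computation with limitation classification,
    alpha and beta diversity of bacterial and fungal communities,
    permutation Mantel tests, stepwise driver regressions with
    permutation importance, and a calibrated synthetic generator for a
    two-region lake-sediment cohort so the full pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    vegan,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
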
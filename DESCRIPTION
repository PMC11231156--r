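Package: blisstox
Title: Bliss-Independence Interaction Tests for Two-Agent Survival Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for synergism or antagonism between two toxicants in binary
    survival bioassays using Bliss independence as the null model. Survivorship
    is fitted with a log-binomial generalized linear model (constrained maximum
    likelihood), so the interaction coefficient is a log survival-ratio whose
    likelihood-ratio test detects departures from independent action, with
    Abbott correction for natural mortality, trial fixed effects, and Holm
    step-down correction across dosages and developmental stages. Includes a
    data model for stage-resolved larval assays, a synthetic-assay generator
    mirroring an 11-group, 3-trial honey bee larval design, and a Monte-Carlo
    harness for type-I error, power, and estimator recovery.
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
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
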
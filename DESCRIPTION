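Package: comorbiscope
Title: Claims-Based Charlson Comorbidity Ascertainment and Non-Cancer Mortality Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to ascertain Charlson comorbid conditions from administrative
    insurance claims under parametrized assessment methods (washout/rule-out
    windows, lookback periods, and claim types), score the Charlson Comorbidity
    Index with the 1987 weights, and estimate sex-adjusted non-cancer mortality
    hazard ratios with left-truncated Cox models on the age timescale. Includes
    a synthetic claims-database generator with known comorbidity truth and
    known hazard structure so that every stage of the pipeline can be validated
    end-to-end without access to restricted claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival (>= 3.5),
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
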
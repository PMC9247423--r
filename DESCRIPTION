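Package: certadjust
Title: Adjusting Cause-of-Death Mortality Trends for Changing Death-Certification Practices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multiple-cause-of-death (MCOD) records and
    adjusting underlying-cause-of-death (UCOD) mortality trends for secular
    changes in death-certification practices, with dementia as the motivating
    cause. Provides ICD-10 cause-group classification, direct age
    standardization, per-stratum logistic models of a cause being selected as
    the underlying cause, counterfactual reference-year adjusted
    age-standardized death rates, a further constant-MCOD rescaling, and a
    synthetic MCOD cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
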
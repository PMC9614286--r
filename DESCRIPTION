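Package: adtgaps
Title: Treatment-Episode Reconstruction and Intermittency Prevalence from
    Drug-Dispensation Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs androgen-deprivation treatment episodes for prostate
    cancer patients from pharmacy dispensation records of depot LHRH analogues,
    detects potentially intermittent interval times (off-treatment gaps of at
    least a configurable minimum length bounded by a confirmed re-initiation),
    and estimates the prevalence of intermittent therapy (annual and global
    P_IAD with Wilson confidence intervals) and the percentage of time off
    treatment (%IAD). Includes a drug/dose to duration-of-action formulary,
    cohort inclusion/exclusion filters with an auditable exclusion log,
    expenditure aggregation normalised as euros per dispensation, a seeded
    synthetic dispensation-data generator with ground truth for validation,
    and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
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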
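Package: pharmprev
Title: Indirect Disease Prevalence Estimation from Drug Dispensing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the prevalence of pharmacologically treated and overall
    Type 2 Diabetes mellitus from aggregated community-pharmacy dispensing
    records. Implements ATC/DDD drug-utilization accounting (total Defined
    Daily Doses and DDD per 1000 inhabitants per day), a six-step sequential
    adjustment model (adherence, therapy concomitance weighting, insulin-user
    exclusion, undiagnosed-fraction correction), a one-at-a-time sensitivity
    engine, and a synthetic dispensing-data generator with person-level ground
    truth for parameter-recovery validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
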
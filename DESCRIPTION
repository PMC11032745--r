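Package: sdli
Title: Street-Drug Lethality Index for Overdose Mortality Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes seizure-based lethality indices for illicit drug
    markets from case-level law-enforcement seizure records and overdose
    death records. Implements per-drug lethality ratios (single-drug
    deaths divided by single-drug seizures in a reference year), the
    per-drug-year Street-Drug Lethality Index (SDLI), the Summed Annual
    Lethality Index (SALI), and a simple linear regression of
    square-root-transformed annual unintentional overdose deaths
    (ICD-10 X40-X44) on SALI, with Durbin-Watson and residual
    diagnostics and back-transformed death predictions. Includes a
    synthetic administrative-record generator with known per-drug
    lethality so the full pipeline can be exercised and validated
    without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    e1071,
    jsonlite,
    lmtest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
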
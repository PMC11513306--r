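Package: dilisignal
Title: Disproportionality Signal Detection and Receptor-Affinity Correlation for Drug-Induced Liver Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacoepidemiologic-pharmacodynamic toolkit for studying
    drug-induced liver injury (DILI) in spontaneous adverse-event reporting
    data. Implements case/non-case disproportionality analysis (reporting
    odds ratio with Wald confidence intervals and the shrinkage information
    component with credibility bounds), the dual ROR/IC signal criterion with
    a minimum-case rule, receptor binding affinity (pKi) and receptor
    occupancy computation from Ki values and unbound plasma concentrations,
    and a drug-level Pearson correlation battery linking reporting odds
    ratios to pharmacodynamic and physicochemical predictors. Includes a
    calibrated generator of synthetic FAERS-like individual case safety
    report tables with known ground-truth reporting odds, so the entire
    pipeline is testable end to end without access to external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
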
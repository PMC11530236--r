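Package: addix
Title: Addiction Index Phenotyping for Extended-Access Self-Administration Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies and classifies addiction-like behavior in large,
    heterogeneous rodent cohorts phenotyped with extended-access drug
    self-administration. Computes per-animal behavioral metrics (escalation of
    intake, progressive-ratio breakpoints, responding despite footshock
    punishment, bottle-brush irritability), normalizes them into cohort-by-sex
    Z-score indices, combines them into a composite Addiction Index, and
    classifies animals as resilient or vulnerable and into severity quartiles.
    Includes a calibrated synthetic-cohort generator with latent ground truth
    for validating every pipeline stage, plus an effect-size, correlation,
    PCA, and power-analysis battery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
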
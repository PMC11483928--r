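Package: gppjourney
Title: Patient-Journey Reconstruction and Drug Survival from Pharmacy Claims
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs patient treatment journeys for generalized pustular
    psoriasis (GPP, ICD-10 L40.1) from longitudinal claims tables: gap-based
    treatment-episode construction, line-of-therapy (LOT) derivation with a
    prioritized drug catalog, time-to-next-therapy (TTNT) and per-drug drug
    survival by an in-package Kaplan-Meier estimator with Greenwood variance
    and log-log median confidence intervals, biologic switching matrices,
    Sankey-style treatment-flow counts, Quan ICD-10 Charlson comorbidity
    scoring, and subgroup stratification.  Ships a synthetic longitudinal
    claims generator with fully known ground truth so every pipeline stage is
    testable without access to proprietary hospital claims databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
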
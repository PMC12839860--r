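Package: pedtriage
Title: Resource-Based Injury Severity Scoring and Undertriage Evaluation
    for Pediatric Trauma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives diagnosis-level severity scores for injured children
    from trauma-registry data: survival risk ratios (the ICD-based Injury
    Severity Score, ICISS) and critical-care risk ratios (the ICD Critical
    Care Severity Score, ICASS), alongside the classic Injury Severity
    Score (ISS) computed from Abbreviated Injury Scale profiles. Classifies
    each patient's need for pediatric trauma center resources (NFPTCR) from
    a composite of timed resource-utilization criteria, and compares the
    discrimination of ISS, ICISS and ICASS for NFPTCR via ROC analysis with
    DeLong confidence intervals and paired AUC tests, threshold
    sensitivity/specificity tables, and descriptive group comparisons. A
    seeded synthetic trauma-registry generator with known diagnosis-level
    outcome propensities supports validation of the whole pipeline without
    access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
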
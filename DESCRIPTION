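Package: eczemaid
Title: Rule-Based Identification and Validation of Atopic Eczema Cases in
    Coded Primary-Care Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying atopic eczema cases in coded primary-care
    electronic health records using declarative diagnosis-plus-treatment rule
    sets, together with the machinery needed to validate such case definitions
    against a physician-confirmed reference standard. Provides a registry for
    categorised clinical code lists (diagnosis tiers, treatment classes,
    exclusions, consults, atopy), a longitudinal cohort model with age
    arithmetic and child/adult stratification, a preset family of case
    definitions of increasing stringency, estimation of age at disease onset
    and last activity from first and last recorded codes, validation
    statistics (positive predictive value with exact binomial confidence
    intervals, detection fractions, stratified group tests, Bland-Altman
    agreement, Wilcoxon rank-sum comparisons), and a seeded generator of
    synthetic coded cohorts with planted ground truth for end-to-end testing
    without access to real records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
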
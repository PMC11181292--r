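Package: ucclaims
Title: Claims-Based Cohort Construction and Outcome Analysis for Elderly-Onset Ulcerative Colitis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds new-onset ulcerative colitis cohorts from administrative
    prescription-claims tables, classifies patients into elderly-onset and
    non-elderly-onset groups, assembles continuous drug-exposure episodes
    under drug-specific scheduled-refill and discontinuation rules, and runs
    the downstream analyses: Kaplan-Meier event-free and treatment-persistence
    curves with log-rank comparisons, Cox proportional-hazards and logistic
    outcome models, and stratified summary tables. Ships a synthetic claims
    generator that emulates the statistical structure of a Japanese
    health-insurance claims database so the whole pipeline is testable
    without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
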
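Package: activeq
Title: Scoring and Validation of a MET-Based Physical Activity Questionnaire
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores a web-based physical activity questionnaire into daily
    energy expenditure using a Metabolic Equivalent Task (MET) catalog,
    computes reference total energy expenditure from doubly labeled water
    (DLW) urine isotope kinetics via the slope-intercept method, and
    quantifies validity (Spearman correlation, Bland-Altman limits of
    agreement) and test-retest reproducibility (one-way ANOVA intraclass
    correlation). Includes a synthetic cohort generator with known ground
    truth so the whole validation pipeline can be exercised end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
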
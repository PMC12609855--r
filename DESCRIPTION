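Package: lipidval
Title: Temporal Validation of Diagnostic Prediction Models for Elevated
    LDL-C and Non-HDL-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the temporal (external) validation of diagnostic
    logistic prediction models for elevated low-density lipoprotein
    cholesterol (LDL-C) and non-high-density lipoprotein cholesterol
    (non-HDL-C), both defined at the 160 mg/dL cut-off. Provides risk
    scoring from published model equations, discrimination (AuROC with
    DeLong confidence intervals) and calibration assessment
    (calibration-in-the-large, calibration slope, expected-to-observed
    ratio, calibration curves), logistic recalibration and refitting,
    decision-curve analysis with net benefit and net reduction in
    investigations, minimum sample-size calculation for external
    validation (C-statistic, calibration slope, and O/E precision
    criteria), case-mix-adjusted benchmark values by bootstrap outcome
    simulation, subgroup fairness assessment, and a synthetic cohort
    generator emulating a hospital-workforce screening population for
    end-to-end pipeline exercises.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    pROC,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
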
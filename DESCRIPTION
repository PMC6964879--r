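Package: smokecast
Title: Forecasting Short-Term Healthcare Expenditure Responses to Changes
    in Smoking Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fixed-effects instrumental-variables panel estimation of the
    log-log relationship between US state smoking behavior (adult current
    smoking prevalence, mean cigarette consumption per smoker) and real per
    capita healthcare expenditure, together with the forecasting workflow
    built on it: recursive out-of-sample one-step-ahead forecast evaluation
    (RMSFE), exhaustive specification search over cross-sectional national
    trend averages with the Model Confidence Set bootstrap elimination
    procedure, bridging of the 2011 BRFSS survey-methodology break, residual
    cointegration and instrument-validity diagnostics, and Monte-Carlo
    counterfactual forecasts of expenditure savings under permanent relative
    reductions in smoking. Includes a seeded synthetic state-panel generator
    emulating the statistical structure of the study data so the full
    pipeline is testable without the proprietary source panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich
Config/testthat/edition: 3
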
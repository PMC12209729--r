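Package: gaitpromis
Title: Fracture-Recovery Trajectories from Instrumented Insoles and PROMIS Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing recovery after lower-leg fracture surgery by
    combining plantar-pressure gait parameters from instrumented insoles with
    PROMIS patient-reported outcomes. Implements threshold-based gait-event
    detection on vertical force signals, zero-phase Butterworth filtering,
    regional plantar-pressure summaries and middle-stride averaging; PROMIS
    Global Health and Pain Interference raw-score and T-score handling with a
    pluggable conversion table; longitudinal analysis-set construction over
    day-interval bins, random-intercept mixed models and interval-wise Spearman
    correlations; and a generalized additive model for location, scale and
    shape with a Box-Cox Cole-Green response and penalized B-spline smooths,
    fitted by penalized maximum likelihood. A synthetic-data module generates
    insole recordings with known ground-truth gait events and longitudinal
    cohorts with known generating parameters so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    signal,
    splines,
    stats,
    lme4,
    lmerTest,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
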
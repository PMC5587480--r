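Package: acmove
Title: Classifying and Modelling Activity-Center Movements from Telemetry Encounters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to discriminate within- versus among-activity-center movements
    of burrowing animals from approximately weekly telemetry encounters, and to
    model the probability of among-activity-center movement. Movement distances
    are classified with Gaussian kernel density estimation and Silverman's
    critical-bandwidth multimodality test, using the intermodal density minimum
    as a per-sex-class distance threshold. The binary movement state is then
    modelled with binomial mixed models (nested individual-within-area random
    intercepts, log encounter-interval offset) under a two-stage BIC selection
    and model-averaging framework. A synthetic-data module generates encounter
    histories, rosters, and daily weather series with known parameters so every
    stage of the pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
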
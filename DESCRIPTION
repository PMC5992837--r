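Package: itsar
Title: Interrupted Time Series Analysis of Drug Pricing Policies with AR(1) Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating pharmaceutical pricing policies with
    interrupted time series designs. Implements two-interruption segmented
    regression estimated by ordinary least squares or exact stationary AR(1)
    maximum likelihood, Durbin-Watson and residual white-noise diagnostics,
    AIC-based model selection, counterfactual forecasting with confidence
    bands, and percent policy-effect summaries. Includes a synthetic
    claims-data generator with known ground truth emulating national health
    insurance prescription claims for antidiabetic drugs, cohort selection
    and monthly aggregation of cost, defined daily doses (DDD) and treated
    patient counts, complication-procedure growth tables, and a
    configuration-driven end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest,
    nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
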
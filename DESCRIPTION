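Package: fibcast
Title: Forecasting Fecal-Indicator Concentrations at Recreational Beaches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A censoring-aware statistical pipeline for nowcasting bacterial and
    viral fecal-indicator concentrations at recreational beaches from routinely
    measured environmental covariates. Implements least-angle regression with the
    lasso modification and model selection by minimum Mallows' Cp, ten-fold
    cross-validated predictive scoring (SRMSEP, predictive R-squared, Overall
    Performance), repeated-imputation Pearson correlation for left-censored
    indicator pairs, covariate-influence scoring across site-indicator models,
    and qPCR standard-curve and delta-delta-Ct quantification with
    data-acceptance quality-control gates. Includes a synthetic-data generator
    for beach-season tables (collinear covariates, sparse log10-linear signal,
    left-censoring) and qPCR runs, so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
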
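Package: weedemerge
Title: Weed Emergence Modelling from Repeat Quadrat Photography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive weed seedling emergence curves from time series of
    quadrat photographs. Implements pixel-based vegetation segmentation on soil
    backgrounds (excess-green thresholding and Gaussian maximum-likelihood
    supervised classification with sunny/overcast reference files),
    postclassification cleanup (circular majority filtering and component
    area filtering), conversion of weed pixel counts into standardized relative
    cumulative emergence series, and nonlinear least-squares fitting of
    logistic, Gompertz, Weibull and biphasic (logistic + Weibull) emergence
    models with AIC/RMSE/R-squared scoring and validation against true
    seedling counts. Includes a synthetic quadrat-scene generator with known
    emergence schedules and ground-truth masks for testing whole pipelines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    png,
    minpack.lm,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
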
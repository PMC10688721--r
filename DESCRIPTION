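Package: fundusex
Title: Sex Differences in Ocular Fundus Photographs of Schoolchildren
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement of 54 geometric and color parameters from color
    fundus photographs (retinal vessel angles at a fixed peripapillary
    circle, vessel-fovea distances and angles, papillomacular geometry,
    optic disc area and ovality, and red-green-blue means with the
    tessellation fundus index in nine circular regions), together with the
    statistical pipeline used to quantify sex differences in those
    parameters: Mann-Whitney screening per school grade, L2-regularized
    (ridge) binomial logistic regression scored by leave-one-out
    cross-validation, AUROC estimation, and paired DeLong comparisons of
    correlated AUROCs with Holm adjustment. A synthetic fundus generator
    draws per-sex feature tables from configurable multivariate normal
    distributions and renders schematic eyes with exact ground-truth
    landmarks so that every measurement can be verified against analytic
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
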
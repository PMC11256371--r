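Package: dustdab
Title: Differential Abundance of House-Dust Metagenome Taxa for Continuous
    Respiratory Outcomes via Debiased Lasso Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for relating indoor-dust metagenome count tables to
    continuous respiratory outcomes (FEV1, FVC, FEV1/FVC, FeNO). Implements
    alpha-diversity association analysis on rarefied counts and a
    high-dimensional differential-abundance procedure in which every taxon
    is tested while controlling for all other taxa and for epidemiological
    covariates: taxon relative abundances enter a Lasso regression with a
    cross-validated penalty, and per-taxon coefficients, standard errors and
    p-values are obtained with the desparsified (debiased) Lasso using
    nodewise regressions. Includes a Dirichlet-multinomial synthetic-data
    generator that emulates the empirical shape of post-classification dust
    metagenome tables, preprocessing (sample/taxon filtering, genus
    aggregation, winsorization, compositional transform, standardization),
    reporting helpers, and simulation studies for type-I error, confidence
    interval coverage and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
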
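Package: vagilong
Title: Longitudinal Analysis of the Vaginal Microbiota in Pregnancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal 16S rRNA gene survey data from the vaginal
    microbiota of pregnant cohorts. Implements Jensen-Shannon divergence
    community state typing with Ward-linkage clustering, per-phylotype
    differential-abundance testing with an AIC-selected ladder of Poisson,
    negative-binomial and zero-inflated negative-binomial mixed-effects
    models (subject random intercepts, log-read-count offsets, adaptive
    Gauss-Hermite quadrature), gestational-age trend analyses (percentile
    interval contrasts and orthogonal-polynomial fits), Shannon-diversity
    comparisons, and a seeded synthetic-cohort generator providing ground
    truth for every pipeline stage.
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
    nlme,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    glmmTMB,
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
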
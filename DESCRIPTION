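Package: longexpo
Title: Modelling Repeated Exposure Biomarkers Against a Binary Outcome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating a repeatedly measured, irregularly timed
    continuous exposure (for example maternal urinary biomarkers across
    pregnancy) to a binary, non-time-varying outcome such as preterm birth.
    Implements nine complementary modelling strategies: simultaneous and
    parallel cross-sectional logistic regression, shrinkage (MAP) logistic
    regression with a temporally correlated Gaussian prior, subject-mean and
    subject-maximum summary models, two-stage mixed-effects models on best
    linear unbiased predictors (BLUPs) and on clusters of BLUPs, a
    reverse-temporal additive mixed model contrasting exposure trajectories,
    Gaussian-mixture and functional k-means clustering of exposure profiles,
    and functional logistic regression on sparse functional principal
    component scores estimated by conditional expectation. Also provides a
    synthetic cohort generator emulating a pregnancy biomarker study and a
    simulation harness measuring type-I error and power under sensitive
    window, elevated average, acute spike, and temporal trend mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    mgcv,
    purrr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
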
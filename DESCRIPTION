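Package: smdvariants
Title: Divergence of Standardized Mean Difference Variants in
    Aggregate-Data Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes four standardized mean difference (SMD) variants --
    endpoint-based (EP/EP) and three change-score variants standardized by
    the baseline, change-score, or endpoint SD -- from aggregate randomized
    trial summaries, over a grid of imputed pre-post correlations. Pools
    each variant with random-effects models (three-level correlated-and-
    hierarchical-effects model with cluster-robust CR2 errors, inverse-
    variance REML with Knapp-Hartung, best/worst-case selection, and
    outlier-excluded pooling), quantifies how strongly variants diverge via
    bivariate random-effects meta-analysis with an unstructured between-
    study covariance and a divergence-slope test against unity, and screens
    study-level moderators of the divergence. Includes a synthetic trial
    generator with known ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    metafor,
    jsonlite,
    yaml,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
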
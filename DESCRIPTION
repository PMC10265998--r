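Package: savsem
Title: Density-Weighted Seagrass Cover Dynamics and Piecewise Structural
    Equation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analyses boom-bust dynamics of submersed aquatic vegetation
    (SAV) mapped by annual aerial surveys. Converts ordinal density
    classes to density-weighted cover, scales cover to the per-site
    maximum, differences it into annual proportional change, and filters
    runs of consecutive zero-cover years. Assigns 30 x 30 m grid cells to
    their nearest monitoring station and aggregates cover by station
    zone. Links watershed loads and spring water-column conditions to
    annual cover change with piecewise structural equation models: one
    linear mixed model per endogenous variable (site random intercept,
    AR(1) residual correlation, maximum likelihood), d-separation basis
    sets, Fisher's C global goodness-of-fit, standardized path
    coefficients, and marginal/conditional R-squared. Includes seeded
    generators for synthetic subestuary and main-channel datasets,
    bay-scale variability statistics (deviance ratios, two-sample
    Kolmogorov-Smirnov comparison), seasonal discharge aggregation, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    igraph,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
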
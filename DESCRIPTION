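Package: edgegrowth
Title: Edge Effects on Temperate Forest Growth and Structure from Inventory Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quasi-experimental pipeline for quantifying how forest edges
    alter tree growth and stand structure in temperate forest inventories.
    Includes a synthetic inventory and landscape generator with known
    ground-truth effect sizes, edge classification of partially forested
    subplots, the filtering cascade used to build inventory analysis datasets,
    greedy 1:1 Mahalanobis nearest-neighbor matching with covariate-balance
    diagnostics, gamma generalized linear models with an inverse link and
    AIC-based model selection, marginal edge effects with delta-method
    confidence intervals and Wald tests, mortality and harvest analyses,
    ecoregion-scale growth scaling from categorical rasters, and global-style
    fragmentation accounting from canopy-cover grids.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
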
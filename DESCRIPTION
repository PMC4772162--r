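Package: phytoregions
Title: Stacked Species Distribution Models, Richness Mapping and
    Phytogeographical Regionalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for delineating botanical richness patterns and
    phytogeographical regions from presence-only occurrence records and
    gridded environmental predictors.  Fits presence-background
    (MaxEnt-style) species distribution models with sample-size-dependent
    feature classes, corrects for collection bias with a null-model AUC
    test, stacks thresholded models into a presence/absence matrix, maps
    and explains species richness (trend-surface variation partitioning,
    stepwise regression, Moran's I), delineates bioregions with beta-sim
    dissimilarity, UPGMA clustering and indicator-species selection of
    the cluster number, and characterizes relative environmental turnover
    with NMDS ordination, environmental vector fitting and the Getis-Ord
    Gi* statistic.  A virtual-species world generator provides known
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
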
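Package: trophlink
Title: Abiotic and Biotic Drivers of Linked Trophic-Level Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-step statistical framework for disentangling abiotic and
    biotic drivers of species assemblages observed at two linked trophic
    levels (e.g. plants and their phytophagous insects). Step 1 fits a
    multiblock redundancy analysis that handles many thematic blocks of
    possibly collinear predictors and ranks blocks and variables by
    importance indices with bootstrap tolerance intervals; per-block
    predictors are screened beforehand by permutation-based forward
    selection with a double-stopping rule, and the other trophic level
    enters as a two-component partial least-squares block. Step 2
    partitions explained community variation into pure abiotic, pure
    biotic, shared and unexplained fractions of adjusted R-squared using
    partial redundancy analysis with permutation tests. Step 3 screens
    species pairs for aggregation and segregation with the C-score under a
    fixed-fixed swap null model, using confidence-limit and empirical
    mean-Bayes criteria. A synthetic community generator with known ground
    truth (environmental blocks, Gaussian niche responses, bottom-up
    coupling, planted co-occurring pairs) supports power and calibration
    studies.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
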
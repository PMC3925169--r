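Package: woodmatch
Title: Pairing Wood Specimens for Choice-Test Bioassays by Fuzzy Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the similarity of wood specimens (veneer discs) from
    three easily measured physical properties (dry weight, moisture absorption
    and the mode skewness of reflected light intensity), groups specimens with
    fuzzy c-means clustering, scores how well the clusters recover known
    source-sheet membership with an ordered neighbour-search statistic,
    benchmarks that score against hypergeometric and bootstrapped-uniform null
    models, and emits matched specimen pairs for choice-test experiments.
    Includes a synthetic-data generator for sheet-structured specimen tables
    and banded disc images so the whole pipeline is testable without external
    data.
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
    nortest,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    e1071,
    EBImage,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
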
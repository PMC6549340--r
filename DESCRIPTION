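Package: combiscreen
Title: Design and Image-Based Analysis of Higher-Order Drug Combination
    Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for exhaustive higher-order drug combination screening
    in 384-well format: randomized plate layout design, label-free
    time-lapse image quantification (confluence, hierarchical-histogram
    morphology, matched-filter object counts), resampling-based intra- and
    inter-plate quality control, higher-order Bliss and scaled-Bliss
    synergy scoring with bootstrap significance, and multilevel K-means
    mining of fused temporal response profiles with non-redundant
    representative combination sets. Includes seeded synthetic-data
    generators so every stage can be exercised without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
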
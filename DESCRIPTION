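Package: asescope
Title: Discovery and Characterization of Autonomous Super-Enhancers from
    Multi-Factor Occupancy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies active enhancers into autonomous super-enhancers
    (aSE), constituent super-enhancers (cSE), dual super-enhancers (dSE)
    and regular enhancers (rEh) from DNase-seq and ChIP-seq peak data. An
    occupancy score multiplies the number of transcription factors and
    cofactors bound at an enhancer by the sum of their min-max normalized
    peak signals; a ranked-curve inflection cutoff separates super-high
    occupancy enhancers, which are then partitioned against a re-implemented
    ROSE classic super-enhancer call (12.5 kb stitching). Companion tools
    characterize enhancer classes by DNase footprint statistics and
    anchoring transcription factors, group chromatin loops into connected
    clusters with span, contact and enhancer-count metrics plus target-gene
    expression, and predict high-occupancy enhancers from single or
    combined factor signals via a two-step (global then local) inflection
    cutoff evaluated with ROC curves. A self-contained synthetic-data
    generator plants ground-truth enhancer classes so the entire pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
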
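Package: mempar
Title: Patterned Chromatin Accessibility and Memory-Specific Expression
    Classes in Human T Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative toolkit for paired RNA-seq and ATAC-seq profiles
    of naive and memory T-cell subsets before and after stimulation.
    Provides negative-binomial Wald differential testing with
    median-of-ratios normalization, fuzzy c-means discovery of gene
    expression modules with data-driven fuzzifier and cluster-number
    selection, a rule-based classifier of patterned accessibility regions
    (conserved, stimulated, primed, memory, naive), an
    expressed/induced/augmented classifier of memory-upregulated genes,
    nearest-TSS peak-to-gene integration with category association
    statistics, position-weight-matrix motif scanning and hypergeometric
    enrichment with rank normalization and bootstrap dendrograms,
    personalized PageRank ranking of transcription-factor importance, and
    SCENITH/Seahorse metabolic metric calculators. A synthetic-data
    generator with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    broom,
    e1071,
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
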
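Package: cellpredict
Title: Inferring Disease-Affected Cell Types from Single-Cell Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores Mendelian diseases against the cell types of their
    affected tissues using single-cell RNA-seq. Disease genes are summarised
    per cell type by the median of their preferential-expression Z-scores
    (the PrEDiCT score), significance is assessed with a gene-set permutation
    null and Benjamini-Hochberg control within each disease, and cell types
    are matched across tissues or species by marker-gene Jaccard overlap.
    Includes literature co-appearance support, enrichment and error-rate
    validation, cell-class susceptibility summaries, and a seedable
    negative-binomial simulator that plants ground-truth disease effects,
    markers and ortholog maps for end-to-end evaluation.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
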
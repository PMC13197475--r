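Package: wingtrait
Title: Attention-Based Prioritisation of Orthogroups for a Binary Wing Trait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies species proteomes as winged or wingless and ranks
    orthologous gene families (orthogroups) by their contribution to the
    classification. Protein sequences are segmented into high-frequency
    amino-acid k-mers, embedded with continuous bag-of-words (CBOW) vectors,
    pooled into per-orthogroup sentence vectors, and fed through a
    bidirectional LSTM with scaled dot-product self-attention. Attention
    weights are aggregated into a per-orthogroup weight table from which the
    top fraction is selected as candidate trait-associated gene families.
    Includes a planted-motif proteome simulator so the full pipeline, and its
    ability to recover known discriminative orthogroups, can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
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
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
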
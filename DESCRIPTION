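Package: netsig
Title: Gene Co-Expression Network Similarity, Signatures and Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-cohort transcriptomic analysis toolkit built around a
    second-order ("correlation of correlations") gene-network similarity
    algorithm. Converts heterogeneous expression units (FPKM, RSEM transcript
    fraction) to TPM, merges cohorts on shared gene symbols into per-sample
    pseudo-TPM, builds gene-network similarity matrices, extracts threshold
    signatures around a query gene (e.g. B7-H3/CD276), compares signature
    distributions, embeds networks in two dimensions with UMAP, runs
    preranked gene-set enrichment (ES, NES, permutation FDR), calls
    single-cell marker positivity fractions, and provides the supporting
    association statistics. Includes a seeded synthetic-data generator that
    plants co-expression modules so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    fgsea,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    uwot
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
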
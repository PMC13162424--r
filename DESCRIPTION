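Package: testistools
Title: Tissue-Specificity Profiling, Clustering and Promoter Motif Mapping
    for Testis Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing testis transcriptomes from multiple
    expression sources. Computes tissue-specificity indices (tau and
    z-score based) from expression atlases and rescales them to a
    symmetric testis-specificity index, assembles a standardized
    gene-by-feature table from per-category specificity profiles of
    several testis datasets, embeds genes in two dimensions (t-SNE or
    UMAP) and clusters the embedding with DBSCAN, classifies
    testis-enriched genes from testis-only expression profiles with
    SMOTE-balanced gradient-boosted trees, and maps position weight
    matrix motifs in TSS-centred promoter windows on both strands with a
    relative-score cutoff. A synthetic-data module generates multi-source
    expression tables, tissue atlases, transcription-factor target lists
    and promoter sequences with planted motifs so the whole pipeline can
    be exercised and verified at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    generics,
    jsonlite,
    Biostrings,
    Rtsne,
    uwot,
    xgboost
Suggests:
    igraph,
    mclust,
    pROC,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
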
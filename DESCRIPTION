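Package: scplpa
Title: miRNA-Disease Association Prediction by Label Propagation and
    Network Consistency Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a binary
    association matrix and MeSH-style disease hierarchies. Builds a
    heterogeneous disease similarity network (information-content semantic
    similarity fused with a Gaussian interaction profile kernel) and a
    heterogeneous miRNA similarity network (functional similarity over
    associated-disease sets with a Gaussian kernel fallback), diffuses the
    known associations over both networks by label propagation, and refines
    the estimated scores by network consistency projection. Ships a full
    leave-one-out cross-validation harness (AUC, AUPR, ACC, MCC, F1, ROC and
    precision-recall curves), cold-start evaluation for new miRNAs and
    isolated diseases, a sequential parameter sweep, and a seeded generator
    of block-structured synthetic fixtures so every stage is testable
    without external databases.
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
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
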
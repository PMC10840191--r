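Package: zgapipe
Title: Transcriptome Pipeline for HDAC-Inhibitor Effects on Early Embryo
    Gene Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested re-implementation of a microarray transcriptome
    workflow for histone-deacetylase-inhibitor treated pre-implantation
    mouse embryos: probe-level flag filtering, robust imputation and
    smooth quantile normalization; per-gene linear-model differential
    expression with Benjamini-Hochberg control; over-representation and
    ranked (running-sum) gene-set enrichment with Jaccard redundancy
    reduction; a Jaccard similarity network over enriched terms with
    k-medoids clustering and TF-IDF/N-gram cluster annotation;
    MCODE-style dense-module detection with Degree/MNC/DMNC/MCC
    centralities and robust rank aggregation of hub genes; fuzzy c-means
    classification of genes into programmed expression waves (maternal,
    minor ZGA, major ZGA, MGA) with Fisher contingency tests; and
    promoter epigenetic-mark enrichment from scored intervals. A
    synthetic-data generator with planted ground truth makes the whole
    pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    GenomicRanges,
    igraph,
    IRanges,
    S4Vectors,
    stats,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
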
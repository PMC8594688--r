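Package: methylomeGWAS
Title: Methylome Segmentation and GWAS-Signal Enrichment for Sperm WGBS
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments whole-genome bisulfite sequencing methylomes into
    hypomethylated regions (sliding-window extension) and partially
    methylated domains (binarized 20-kb windows decoded by a two-state
    hidden Markov model), tests 500-bp tiles for group methylation
    differences by binomial likelihood-ratio logistic regression with
    Benjamini-Hochberg adjustment, and links methylation alterations to
    GWAS signals of fertility traits through a sum-of-t-squared marker-set
    test with a cyclical-permutation null and count-based hypergeometric
    window-set enrichment. Includes a synthetic-data generator that plants
    hypomethylated blocks, partially methylated domains, differential
    tiles and enriched GWAS regions with a recoverable ground truth, and
    an end-to-end deterministic pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
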
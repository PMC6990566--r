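Package: svhic
Title: Effects of Common Structural Variants on Hi-C Chromatin Contacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cohort-scale analysis of how common structural variants
    (deletions and inversions) reshape 3D chromatin contacts measured by
    Hi-C. Provides S4 containers for binned per-sample contact matrices,
    covariate-based and band-wise cross-sample normalization with batch
    correction, directionality-index TAD boundary calling with a
    Gaussian-emission hidden Markov model, span/flank association testing
    of deletion dosage against contact intensity with ancestry and sex
    covariates, permutation nulls and genomic-inflation calibration,
    per-bin regression coefficient maps, inversion genotype correlation
    maps with mirrored-matrix visualization, and a synthetic Hi-C cohort
    generator with ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    png,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
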
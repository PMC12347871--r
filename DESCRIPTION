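Package: cmaMRD
Title: Chromosomal Microarray Aberration Analysis for MRD Risk in B-ALL
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering copy-number and copy-neutral LOH biomarkers
    of minimal residual disease (MRD)-positive remission in B-cell acute
    lymphoblastic leukemia from segment-level chromosomal microarray calls.
    Provides QC and size filtering of aberration segments, binary gene-by-event
    feature encoding via genomic overlap, random-forest feature ranking with a
    label-permutation significance test, per-feature Fisher exact statistics
    with multiple-testing correction, co-localized aberration cluster
    detection, sex/age triple-matched reference comparison, a synthetic cohort
    generator that reproduces the assumed study structure, and a reproducible
    end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
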
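Package: senomics
Title: Trajectory Analysis of Multi-Omic Time Courses in Replicative Senescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ordered-passage (time-course) RNA-seq, reduced
    representation bisulfite sequencing (RRBS) and ATAC-seq experiments of the
    kind used to characterise replicative senescence in primary cell culture.
    Implements monotonic-trajectory classification of differential features,
    per-cytosine differentially methylated site (DMS) calling by adjacent-passage
    deltas replicated across independent sample series, consensus peak-atlas
    construction with a replicate-presence rule, appearing and disappearing peak
    detection, promoter and enhancer annotation, position weight matrix scanning
    with hypergeometric motif enrichment against a peak background, aggregate
    transcription-factor footprint profiles, and pioneer/settler/migrator factor
    classification from chromatin dependence and chromatin opening index values.
    A seeded synthetic-data generator with planted ground truth exercises every
    stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
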
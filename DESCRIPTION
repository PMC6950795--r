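Package: methexpr
Title: Integration of DNA Methylation and Gene Expression in Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-cohort integration of Illumina beta-value DNA methylation
    arrays with gene expression to classify genes into regulation-pattern
    groups (UPUP, UPDOWN, DOWNUP, DOWNDOWN), refine them into "-only" groups
    on a dense probe manifest, correlate probe methylation with expression on
    matched samples, and characterise probes by distance to the transcription
    start site, CpG-island context and gene-region location. Includes a
    synthetic-data generator with planted regulation-group structure so the
    whole pipeline is testable without external cohorts, per-probe Welch or
    pooled two-sample tests for differential methylation, cross-cohort
    consensus calling, and readers/writers for beta matrices, sample sheets,
    Illumina-style manifests and BED12 gene models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
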
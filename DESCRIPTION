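Package: ploidyscan
Title: Ploidy, Copy-Number and Variant-Landscape Analysis from Depth and Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers genome-wide and segmental ploidy of polyploid resequencing
    samples from reference-allele-frequency spectra, detects copy-number
    segments from windowed read depth with masking of reference N-gap
    artifacts, applies GATK-style hard filters to variant calls, and
    characterizes the variant landscape (density tracks, InDel frame-
    preservation bias inside coding sequence, high-impact effect classes).
    Includes a synthetic triploid-genome generator with a machine-readable
    truth set so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
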
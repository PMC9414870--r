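Package: seedqtl
Title: Seed Image Morphometry and QTL Mapping for Biparental RIL Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for dissecting the genetics of cereal seed
    size, shape and coat color from digital images. From photographs of seeds
    scattered on a white background with a 24-patch color calibration card, it
    extracts 55 per-seed descriptors (3 size, 4 shape, 48 color, the latter as
    mean and dominant-cluster colors in the RGB, HSV, Lab and YCrCb spaces),
    aggregates them per genotype, and maps them in a recombinant inbred line
    population by inclusive composite interval mapping: stepwise cofactor
    selection, an additive 1-cM scan, and a digenic epistasis scan. Traits are
    then clustered by the overlap of their QTL locations (Ochiai index, UPGMA),
    and candidate genes inside highly significant QTL intervals are prioritized
    by annotation confidence, seed expression and KEGG-orthogroup membership.
    A synthetic-data module renders seed scenes with exact ground truth and
    simulates RIL genotypes and phenotypes with planted QTLs so that every
    stage of the pipeline can be validated against known answers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    grDevices,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
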
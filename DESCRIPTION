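Package: ervprofiler
Title: Repeat-Element Epigenomic Profiling of Endogenous Retroviruses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for profiling repressive chromatin marks over
    transposable-element families at desk scale: ChIP-seq metaprofiles along
    endogenous retrovirus (ERV) consensus sequences with random multi-mapper
    assignment, directional read extension and per-bin RPKM normalization;
    agglomerated element-relative read-density profiles in the genomic
    regions flanking intact elements, with quality/uniqueness filtering,
    positional deduplication and a k-mer mappability check; bisulphite clone
    methylation calling with conversion-rate QC and four-category binning;
    in-silico PCR primer-site enumeration; and delta-delta-Ct qPCR /
    ChIP-qPCR enrichment statistics. A seeded synthetic-data generator
    builds toy genomes with planted ERV copies, enriched read libraries,
    bisulphite clone sets and Ct tables so that every stage can be verified
    against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
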
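Package: grnakit
Title: Guide RNA Design and Long-Range Deletion Analysis for Type I-B
    CRISPR Editing in Thermophiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational toolkit for type I-B CRISPR-Cas3 genome editing
    in thermophilic bacteria such as Parageobacillus thermoglucosidasius.
    Enumerates TTA-PAM-anchored protospacer candidates genome-wide, scores
    GC content and melting temperature, and builds the per-gene lowest-GC
    guide RNA selection manual that exploits the negative correlation
    between guide GC content and editing efficiency. Infers deletion
    breakpoints, microhomology and junction insertions from Sanger junction
    reads, aggregates deletion intervals into genome-coverage and
    non-essential-gene statistics, and selects screening representatives
    from protein homolog sets via greedy identity clustering and
    neighbor-joining trees. A fully seeded synthetic-data generator
    (genomes, annotations, Cas3-style deletion junction reads, homolog
    families with planted identities) makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
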
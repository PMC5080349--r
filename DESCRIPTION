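Package: ssrqtl
Title: In Silico Polymorphic SSR Marker Discovery and Integrated SSR/SNP QTL-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide discovery of perfect microsatellite (SSR) markers that
    are polymorphic in silico across a panel of accession genomes, with
    gene-context annotation, reading-frame effect prediction for coding-region
    repeat variants, cis-regulatory motif disruption scanning, marker diversity
    statistics (PIC, Nei-Li distance, neighbor-joining trees), and a
    bulked-segregant QTL-seq workflow built on an integrated SNP/SSR index with
    sliding-window profiles and Monte-Carlo null confidence intervals. Includes
    a synthetic-data generator for accession panels and selfed biparental
    mapping populations so the whole workflow can be exercised end to end with
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    methods,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
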
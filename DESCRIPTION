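Package: centrosynteny
Title: Comparative Centromere Genomics for Genome Pairs with Contrasting Centromere Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing the centromere organisation of two related
    genomes: classification of conserved single-copy ortholog links from
    tabular protein alignment hits, chaining of links into synteny blocks with
    inversion and inter-chromosomal translocation calling, cross-genome
    projection of centromere intervals to classify centromere origins
    (corresponding versus de novo insertion), satellite monomer
    characterisation (dyad symmetries, stem-loop scoring, shared motifs,
    monomer tiling of arrays, higher-order repeat period detection), and
    ChIP/input enrichment statistics per repeat cluster and per genomic
    window. A seeded synthetic-data generator plants orthologs,
    rearrangements, centromere insertions, satellite structure and ChIP
    enrichment with full truth tables so every step is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
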
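Package: sbsites
Title: Sleeping Beauty Transposon Integration-Site Simulation, Calling and
    Region Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale analysis pipeline for Sleeping Beauty (SB)
    transposon integration-site studies. Builds synthetic genomes with
    acrocentric, nucleolus-organizer-like structure, samples ground-truth
    insertions from an explicit TA-dinucleotide target model with
    configurable region-level targeting bias, simulates paired-end
    junction-library sequencing reads (sonication shear, size selection,
    PCR duplication, sequencing error, plasmid-backbone contamination),
    cleans and merges reads, maps junctions with a k-mer seed-and-verify
    aligner under unique and random multimapper regimes, calls insertion
    sites with read-support thresholds, and quantifies region-level
    enrichment between transposase conditions with Fisher's exact test,
    binned RPKM insertion-density profiles, TA-density profiles and
    target-site sequence logos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
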
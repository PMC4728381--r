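Package: hmcpeaks
Title: Genomic-Element Profiling and Gene-Level Scoring of 5-hmC Enrichment Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of 5-hydroxymethylcytosine (5-hmC) enrichment
    sequencing in compact invertebrate genomes such as Daphnia pulex. Partitions a
    genome annotation into element classes (CDS exons, introns, nested TSS-upstream
    and TES-downstream windows), computes tags-per-kilobase peak densities over
    those classes, scores genes with PPKM (peaks per kilobase of protein-coding
    sequence per million peaks), classifies genes into hydroxymethylated and void
    groups, compares GO-term frequencies between the groups with Fisher's exact
    test, and quantifies locus-level percent modification from
    methylation-sensitive restriction-enzyme qPCR. A synthetic-data module
    generates genomes, peaks, GO annotations and qPCR plates with known truth so
    every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
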
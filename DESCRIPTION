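Package: metassemblr
Title: Transcriptome Meta-Assembly Construction and Quality Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds de novo transcriptome meta-assemblies by concatenating
    candidate assemblies and removing every contig that is a substring of
    another contig (forward or reverse-complement), and evaluates competing
    assemblies with seven quality metrics: N50, median contig length,
    marker-gene recovery, percentage of contigs with homology to a reference
    CDS set, number of reference CDS detected, number of CDS covered to at
    least 95 percent of their length, and the percentage of reads
    pseudo-aligned back to the assembly. Metrics are min-max normalized to
    [0,1], summed, and assemblies ranked by the summed score; CDS detection
    is decomposed into exclusive set-overlap regions across assemblies.
    Includes six-frame ORF scanning, a seed-and-extend CDS coverage engine,
    k-mer pseudo-alignment, and a synthetic-data generator with full
    ground-truth provenance for testing on IonTorrent-like single-end data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
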
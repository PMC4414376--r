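Package: microsynt
Title: Microsatellite-Anchored Synteny and Comparative Statistics for Draft Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects microsatellite (SSR) loci in a pair of draft genome
    assemblies, identifies one-to-one homologous loci by flanking-sequence
    similarity, chains them into order- and orientation-consistent synteny
    blocks, and classifies intra- and inter-chromosomal rearrangements.
    Also computes standard assembly summary statistics (N50, contig counts),
    protein-domain expansion/contraction and repeat-number statistics from
    Pfam-style domain tables, and CpG observed/expected depletion-based DNA
    methylation prediction. Ships a synthetic-data generator that produces
    assembly pairs with a known rearrangement history, domain tables with
    implanted expansions, and two-class CpG gene sets, so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
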
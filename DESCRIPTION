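Package: pgalign
Title: Protein-to-Genome Spliced Alignment and Gene Structure
    Reconstruction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps protein queries onto eukaryotic genomic DNA and
    reconstructs exon-intron gene structures.  The core is a
    penalty-scored spliced Needleman-Wunsch dynamic programme over a
    protein and a nucleotide sequence that models codon matches,
    insertions, gaps, frameshifts and introns (including introns that
    split codons), with splice-site-dependent intron penalties.  Around
    it, a hit-processing pipeline refines seeded local matches: exon
    margins are trimmed and realigned, unmatched regions are classified
    as insertions or introns, short and divergent exons are recovered by
    exhaustive alignment, terminal exons are found by exact pattern
    search, splice sites are classified as canonical or doubtful, and
    genes spread across several contigs of fragmented assemblies are
    stitched together.  A synthetic-fixture generator produces genomes
    with known gene structures (micro-exons, non-canonical splice sites,
    sequence divergence, frameshifts, contig breaks) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    graphics,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
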
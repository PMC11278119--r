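Package: larkCR
Title: Comparative Analysis of Lark Mitochondrial Control Regions and Gene Orders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of avian mitochondrial genomes
    carrying a duplicated control region, centred on the lark (Alaudidae)
    situation of a complete CR1 plus a remnant second control region (rCR2)
    composed almost entirely of tandem repeats. Provides gene-order
    extraction and classification on circular genomes, enumeration of
    tandem-duplication-random-loss (TDRL) rearrangement scenarios,
    detection and decomposition of control-region tandem repeats into
    5' non-repeat / repeat array / 3' non-repeat segments, repeat-unit
    haplotype and consensus analysis with local-alignment identity,
    a seven-pattern homology scan of repeat-derived sequences against the
    whole mitogenome, parsimony mapping of gene-order traits on a supplied
    phylogeny, nucleotide composition and codon-usage statistics, and a
    synthetic mitogenome simulator with full ground truth for testing
    every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
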
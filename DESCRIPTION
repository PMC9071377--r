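Package: cucurbHLH
Title: Comparative Genomics of the bHLH Transcription-Factor Family in Cucurbits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a comparative-genomics workflow for the
    basic helix-loop-helix (bHLH) transcription-factor family across multiple plant
    genomes. Locates the bHLH domain with a position-specific scoring profile,
    partitions it into basic/helix1/loop/helix2 regions, classifies predicted
    DNA-binding ability (non-binding, non-E-box, E-box non-G-box, G-box) and
    intron-distribution patterns; chains homology anchors into collinear blocks by
    sparse dynamic programming and derives ortholog groups, paralog pairs and
    tandem-duplicate clusters; estimates Ka/Ks by the Nei-Gojobori (1986) counting
    method with Jukes-Cantor correction; builds neighbor-joining trees with
    bootstrap support, assigns clades, and infers lineage-specific cluster
    expansions from synonymous divergence; calls tissue-predominant expression from
    FPKM matrices. A pangenome simulator with full ground truth (shared ancient
    tetraploidy, lineage whole-genome duplication, tandem duplication, loss,
    codon-level sequence evolution at controlled dN/dS, planted binding categories,
    intron patterns and tissue-biased expression) makes every stage testable
    without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
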
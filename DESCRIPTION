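Package: ervscan
Title: Characterization of Endogenous Retrovirus Loci from Repeat Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles endogenous retrovirus (ERV) loci from RepeatMasker-style
    repeat annotation of a genome, classifies each locus as full-length,
    solo-LTR or truncated, detects target-site duplications and the fixed LTR
    terminal motifs, assigns LTRs to subfamily consensus sequences and flags
    chimeric (recombinant) proviruses, dates insertions from 5'-3' LTR
    divergence under the Kimura 2-parameter model, profiles the genomic
    environment (flanking GC content, gene density, genic context), scans
    proviral structure (gag ORF integrity, primer-binding site, polypurine
    tract), and builds a bootstrapped neighbor-joining phylogeny of LTR
    sequences. A synthetic-genome generator plants ERV insertions with full
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
SystemRequirements: mafft (for multiple alignment)
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
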
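Package: rtscreen
Title: Genome-Wide Screening for Readthrough-Derived Peroxisomal Protein Isoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate peroxisomal protein isoforms generated by
    translational readthrough of stop codons. Extracts in-frame C-terminal
    extensions downstream of annotated stop codons from a genome (FASTA) and
    its annotation (GFF3), classifies each stop codon context against the
    leaky TGA-CT readthrough element, scans translated extensions for
    C-terminal peroxisomal targeting signals (PTS1) with an enumerable
    tripeptide motif model, and tabulates conservation of the targeting
    mechanism across ortholog groups. Includes a synthetic genome generator
    with planted readthrough-PTS1 genes and decoy classes so the full
    pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    dplyr,
    tibble,
    purrr,
    readr,
    ggplot2,
    rlang,
    generics,
    stats,
    methods
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
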
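Package: rdnavar
Title: Intragenomic Ribosomal DNA Variation from Long-Read Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies intragenomic variation of the fungal rDNA cistron
    (ITS and D1-D2 LSU) from long-read circular-consensus amplicon data and
    performs distance-based species identification. Provides CCS-level
    quality filtering, dual-barcode demultiplexing with mismatch tolerance,
    primer-anchored cleaving of full-length amplicons into ITS and LSU
    barcodes, greedy identity clustering with star-alignment majority-rule
    consensus calling, uncorrected p-distance divergence summaries,
    minimum spanning haplotype networks, and nearest-reference
    classification against curated Sanger panels. Ships a synthetic
    amplicon generator that emulates multi-copy rDNA pools with dominant
    and minor variants, so the whole pipeline is testable against known
    truth without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
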
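Package: digenomer
Title: Cleavage-Site Calling and Indel Quantification for Cpf1 Digenome-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the genome-wide specificity and editing
    efficiency of CRISPR-Cpf1 (Cas12a) nucleases from sequencing data.
    Implements strand-specific read 5'-end pileups from in-vitro-digested
    whole-genome sequencing alignments, per-position DNA cleavage scoring
    under a staggered-cut model (5' overhangs of 1-5 nt) with cutoff-based
    site calling, PAM-anchored mismatch-tolerant enumeration of candidate
    off-target sites, and amplicon deep-sequencing indel quantification with
    in-frame versus out-of-frame classification. A seeded simulation kit
    generates synthetic genomes, digestion reads, and amplicon reads so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    withr,
    yaml,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
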
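Package: genestructr
Title: Exact Gene-Structure Reconstruction and Alternative-Splicing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the exact exon-intron structure of a protein query
    on genomic sequence, annotating mismatches, sequence shifts, in-frame
    stop codons and unmatched regions; maps cDNA/EST evidence onto the
    reconstructed gene in a two-step procedure and classifies every class of
    alternative-splicing event (alternative 5'/3' splice sites, exon
    skipping, intron retention, novel exons); predicts mutually exclusive
    exon candidates and tandemly arrayed gene duplicates with fused and
    split exon homologies. Includes a deterministic synthetic-locus
    generator with known ground truth, GFF3/YAML/FASTA/SVG export, and
    tidy accessors for all results.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    generics,
    tidyr,
    purrr,
    stringr,
    rlang,
    yaml,
    ggplot2,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
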
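Package: markertree
Title: Single-Copy Marker Gene Identification and Concatenated Protein
    Species Trees for Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies single-copy marker genes shared by a set of
    (possibly draft or incomplete) prokaryotic genomes from profile-HMM
    annotations, builds a trimmed concatenated protein alignment from the
    markers, and infers a bootstrapped neighbor-joining species tree.
    Consumes per-genome protein FASTA files and HMMER3 domain tables,
    applies a best-hit e-value filter, selects PFAM profiles that are
    single-copy in every genome, aligns each marker family with a built-in
    progressive aligner (or an external aligner), removes highly variable
    or gapped alignment blocks, and writes the marker list, alignments,
    partition map and Newick tree. Marker profiles can additionally be
    mapped to COG functional categories through shared Gene Ontology
    terms. A seeded simulator generates genome sets with known marker
    structure and a known species tree for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    stats
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
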
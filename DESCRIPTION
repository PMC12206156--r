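Package: viralign
Title: Iterative Alignment-Graph Assembly and Polishing of Viral Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-guided assembly and polishing of small (viral-scale)
    genomes from long or short sequencing reads. Reads are threaded onto a
    backbone genome to build a weighted directed acyclic alignment graph in
    which edge weights count supporting reads; the maximum total-weight path
    is extracted by dynamic programming and used as the backbone for the next
    round, iterating until the assembly reaches a fixpoint. Includes a
    built-in seed-and-extend banded read aligner (no external binaries
    required), SAM/BAM import for externally produced alignments, assembly
    evaluation metrics (genome fraction, mismatches, indel events and length,
    edit distance, similarity), and a seeded read simulator for linear viral
    genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
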
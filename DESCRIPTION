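Package: orthomapper
Title: Orthology-Aware Functional Annotation of Proteins and Contigs
Version: 0.1.0
Authors@R:
    person("orthomapper", "developers", email = "orthomapper@example.org",
           role = c("aut", "cre"))
Description: A self-contained workflow for functional annotation of protein
    and nucleotide sequences by orthology. Predicts prokaryotic open reading
    frames from assembled contigs, searches queries against a compact
    reference database of proteins organised into hierarchical orthologous
    groups with a seed-and-extend Smith-Waterman aligner (fast, sensitive and
    iterative presets, plus a blastx-like six-frame mode), resolves the
    taxonomic scope of annotation transfer over a taxonomy tree, classifies
    pairwise ortholog types (one-to-one through many-to-many), transfers
    per-source functional terms from orthologs while excluding in-paralogs,
    and annotates protein domains in three modes (transfer from orthologs,
    realignment refinement, and de novo position-specific scoring matrix
    scanning with gathering thresholds and clan competition). Includes a
    gene duplication-loss simulator that generates ground-truth reference
    databases and held-out query sets so every stage can be benchmarked
    offline, plus writers for tabular reports and GFF3 decoration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
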
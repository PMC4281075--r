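Package: binpairs
Title: Mate-Pair Aware Reconciliation of Taxonomic Read Assignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Post-hoc reconciliation of per-read taxonomic assignments of
    paired-end metagenomic reads. When the two mates of a pair are assigned to
    divergent lineages both are moved to their lowest common ancestor; when
    they sit at different depths of one lineage, four rank-algebra strategies
    (SI-SIV) trade specificity against confidence. Includes an NCBI-style
    taxonomy loader with lineage/LCA/rank operations, a paired-end metagenome
    read simulator with per-read truth labels (Roche-like fragments, short
    clones, long clones with a per-base substitution error model), a k-mer
    fixture binner for end-to-end testing, a rank-bucketed accuracy evaluator,
    and a command-line interface wiring them into a simulate-bin-reconcile-
    evaluate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
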
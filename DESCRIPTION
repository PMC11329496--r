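Package: editclust
Title: Edit-Cluster Analysis for Antibody-Directed RNA Base-Editing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls C-to-U RNA edit sites from per-site pileup evidence, detects
    regions statistically enriched for edits with a Poisson window model and
    Benjamini-Hochberg FDR control, derives confident edit clusters by
    strand-aware replicate intersection and control subtraction, and evaluates
    binding specificity through within-feature permutation enrichment of RNA
    binding protein motifs, nearest-motif distance distributions, reference
    peak overlap and edit-radius estimation. Includes isoform-resolved edit
    quantification (editsC) from long reads and a fully seeded synthetic-data
    generator that emulates antibody-directed deaminase editing with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
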
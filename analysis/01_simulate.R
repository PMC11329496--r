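#!/usr/bin/env Rscript
## Simulate the reference study conditions and write the fixture bundle:
## a ~1 Mb stranded toy transcriptome (100 genes, both strands), 30 planted
## UGCAUG binding sites with a 200 nt editing radius, 50 planted SNPs, and
## per-site count tables for case / enzyme-only / buffer-only x 3 replicates.
##
## Usage: Rscript analysis/01_simulate.R [seed]

library(editclust)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- file.path("results", "sim")

cfg <- sim_config(seed = seed)
ref <- generate_reference(cfg)
paths <- write_fixture_bundle(ref, out)

message(sprintf("genome: %d nt on %s", Biostrings::width(ref$genome),
                names(ref$genome)))
message(sprintf("genes: %d (%d on '+', %d on '-')",
                nrow(ref$annotation$genes),
                sum(ref$annotation$genes$strand == "+"),
                sum(ref$annotation$genes$strand == "-")))
message(sprintf("planted motifs: %d  planted SNPs: %d  transcribed C sites: %d",
                nrow(ref$truth$motifs), nrow(ref$truth$snps),
                nrow(ref$c_sites)))
message("bundle written under ", out, ":")
for (p in unlist(paths)) message("  ", p)
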
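#!/usr/bin/env Rscript
## Evaluate binding specificity of the confident clusters: UGCAUG
## containment versus 20 within-feature shuffles (z-score and fold
## enrichment), nearest-motif distance distributions, recovery of the
## planted binding sites, and the editing-radius estimate from per-site
## distances (case vs enzyme-only).
##
## Usage: Rscript analysis/05_enrichment.R [seed]  (after 04_confident_clusters.R)

library(editclust)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

sim_dir <- file.path("results", "sim")
out <- file.path("results", "enrichment")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- Biostrings::readDNAStringSet(file.path(sim_dir, "genome.fa"))
names(genome) <- sub("\\s.*$", "", names(genome))
annotation <- read_gtf(file.path(sim_dir, "annotation.gtf"))
truth <- read_bed(file.path(sim_dir, "truth_motifs.bed"))

hits <- scan_motif(genome, annotation, "UGCAUG")
message(sprintf("UGCAUG occurrences inside genes: %d (%d planted)",
                nrow(hits), nrow(truth)))

summaries <- list()
for (cond in c("case", "enzyme_only")) {
  conf <- read_bed(file.path("results", "confident",
                             paste0("confident_", cond, ".bed")),
                   extra_cols = c("p_value", "q_value"))
  if (!nrow(conf)) {
    message(cond, ": no confident clusters, skipped")
    next
  }
  enr <- motif_enrichment(conf, hits, annotation, n_perm = 20, seed = seed)
  summaries[[cond]] <- data.frame(
    condition = cond, n_clusters = nrow(conf),
    observed = enr$observed_fraction,
    perm_mean = mean(enr$permuted_fractions),
    perm_sd = sd(enr$permuted_fractions),
    z = enr$z_score, enrichment = enr$enrichment,
    stringsAsFactors = FALSE
  )
  d <- nearest_feature_distance(conf, hits)
  write.table(data.frame(distance = d),
              file.path(out, paste0("nearest_motif_distance_", cond, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%-12s motif fraction %.3f vs permuted %.3f +/- %.3f -> z = %.2f, enrichment = %.2f",
    cond, enr$observed_fraction, mean(enr$permuted_fractions),
    sd(enr$permuted_fractions), enr$z_score, enr$enrichment))
}
write.table(do.call(rbind, summaries), file.path(out, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## recovery of planted sites by the confident case clusters
conf_case <- read_bed(file.path("results", "confident", "confident_case.bed"),
                      extra_cols = c("p_value", "q_value"))
mg <- GenomicRanges::GRanges(truth$chrom,
                             IRanges::IRanges(pmax(truth$start0 - 199L, 1L),
                                              truth$end0 + 200L),
                             truth$strand)
cg <- GenomicRanges::GRanges(conf_case$chrom,
                             IRanges::IRanges(conf_case$start0 + 1L,
                                              conf_case$end0),
                             conf_case$strand)
rec <- mean(GenomicRanges::countOverlaps(mg, cg, ignore.strand = FALSE) > 0)
message(sprintf("planted motifs within 200 nt of a confident case cluster: %.0f%%",
                100 * rec))

## editing radius from per-site nearest-motif distances
edits_of <- function(key) {
  read.table(file.path("results", "edits",
                       paste0("edit_sites_", key, ".tsv")),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
site_iv <- function(s) data.frame(chrom = s$chrom, start0 = s$pos0,
                                  end0 = s$pos0 + 1L, strand = s$strand,
                                  stringsAsFactors = FALSE)
d_case <- nearest_feature_distance(site_iv(edits_of("case_rep1")), hits)
d_enz <- nearest_feature_distance(site_iv(edits_of("enzyme_only_rep1")), hits)
radius <- edit_radius(d_case, d_enz)
write.table(data.frame(radius_nt = radius),
            file.path(out, "edit_radius.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("editing radius estimate: %d nt (planted: 200 nt)", radius))
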
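#!/usr/bin/env Rscript
## Call and filter C-to-U edit sites from the simulated count tables.
## The scoring background is the pooled buffer-only edit fraction; sites are
## kept with confidence score > 0.5, edit fraction < 0.8 and no known-SNP
## overlap, and written as per-replicate TSVs under results/edits/.
##
## Usage: Rscript analysis/02_call_edits.R   (after 01_simulate.R)

library(editclust)

sim_dir <- file.path("results", "sim")
out <- file.path("results", "edits")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

snps <- read_bed(file.path(sim_dir, "truth_snps.bed"))
conds <- c("case", "enzyme_only", "buffer_only")
counts <- list()
for (f in list.files(sim_dir, pattern = "^sites_.*\\.tsv$")) {
  counts[[sub("^sites_(.*)\\.tsv$", "\\1", f)]] <-
    read_site_counts(file.path(sim_dir, f))
}

buffer_tabs <- counts[grep("^buffer_only", names(counts))]
p_bg <- global_edit_fraction(buffer_tabs)
message(sprintf("scoring background (pooled buffer-only): %.3g", p_bg))

for (key in names(counts)) {
  called <- call_edit_sites(counts[[key]], p_bg)
  kept <- filter_edit_sites(called, snps)
  write.table(kept, file.path(out, paste0("edit_sites_", key, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%-22s %6d candidate sites -> %6d after filtering (%.0f%%)",
                  key, nrow(called), nrow(kept), 100 * nrow(kept) / nrow(called)))
}
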
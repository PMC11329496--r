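#!/usr/bin/env Rscript
## Detect edit clusters per replicate: 50 nt windows stepped by 10 nt over
## annotated segments, Poisson site-count statistics against per-region-class
## background rates estimated from the buffer-only control, BH-FDR at 0.1,
## and merging of significant windows within 15 nt.
##
## Usage: Rscript analysis/03_call_clusters.R   (after 02_call_edits.R)

library(editclust)

sim_dir <- file.path("results", "sim")
edits_dir <- file.path("results", "edits")
out <- file.path("results", "clusters")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

annotation <- read_gtf(file.path(sim_dir, "annotation.gtf"))
keys <- sub("^edit_sites_(.*)\\.tsv$", "\\1",
            list.files(edits_dir, pattern = "^edit_sites_"))
sites <- lapply(setNames(keys, keys), function(k) {
  read.table(file.path(edits_dir, paste0("edit_sites_", k, ".tsv")),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
})
counts <- lapply(setNames(keys, keys), function(k) {
  read_site_counts(file.path(sim_dir, paste0("sites_", k, ".tsv")))
})

buffer_keys <- grep("^buffer_only", keys, value = TRUE)
bg <- estimate_background_rate(sites[buffer_keys], counts[buffer_keys],
                               annotation)
message("background edit-site rates per covered C (buffer-only):")
for (nm in names(bg)) message(sprintf("  %-10s %.5f", nm, bg[[nm]]))

model <- cluster_model(p_bg = bg)
for (k in keys) {
  cl <- call_edit_clusters(sites[[k]], counts[[k]], annotation, model)
  write_bed(cl, file.path(out, paste0("clusters_", k, ".bed")),
            extra_cols = c("p_value", "q_value"))
  message(sprintf("%-22s %5d clusters (median width %s nt)", k, nrow(cl),
                  if (nrow(cl)) median(cl$end0 - cl$start0) else "-"))
}
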
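#!/usr/bin/env Rscript
## Derive confident edit clusters: strand-aware intersection of the three
## case (and enzyme-only) replicates anchored on replicate 1, then removal of
## every cluster overlapping a buffer-only cluster.
##
## Usage: Rscript analysis/04_confident_clusters.R   (after 03_call_clusters.R)

library(editclust)

cl_dir <- file.path("results", "clusters")
out <- file.path("results", "confident")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

read_cl <- function(key) {
  read_bed(file.path(cl_dir, paste0("clusters_", key, ".bed")),
           extra_cols = c("p_value", "q_value"))
}
keys <- sub("^clusters_(.*)\\.bed$", "\\1",
            list.files(cl_dir, pattern = "^clusters_"))
buffers <- lapply(grep("^buffer_only", keys, value = TRUE), read_cl)

for (cond in c("case", "enzyme_only")) {
  reps <- lapply(sort(grep(paste0("^", cond, "_rep"), keys, value = TRUE)),
                 read_cl)
  inter <- intersect_replicates(reps)
  conf <- subtract_control(inter, buffers)
  write_bed(conf, file.path(out, paste0("confident_", cond, ".bed")),
            extra_cols = c("p_value", "q_value"))
  message(sprintf(
    "%-12s %5d clusters in the anchor replicate -> %5d intersected -> %5d confident (%.1f%% removed)",
    cond, nrow(reps[[1]]), nrow(inter), nrow(conf),
    100 * (1 - nrow(conf) / max(nrow(reps[[1]]), 1))))
}
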
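#' Exonic sense-C positions per transcript
#' @noRd
.tx_c_positions <- function(reference) {
  ann <- reference$annotation
  cs <- reference$c_sites
  out <- list()
  for (tid in ann$transcripts$transcript_id) {
    fx <- ann$features[ann$features$transcript_id == tid &
                         ann$features$type %in% .exonic_types(), ]
    gid <- ann$transcripts$gene_id[ann$transcripts$transcript_id == tid]
    pos <- cs$pos0[cs$gene_id == gid]
    keep <- rep(FALSE, length(pos))
    for (k in seq_len(nrow(fx))) {
      keep <- keep | (pos >= fx$start0[k] & pos < fx$end0[k])
    }
    out[[tid]] <- pos[keep]
  }
  out
}

#' Simulate full-length long reads with isoform assignments
#'
#' Each read covers all exonic sense-C positions of its isoform; per-position
#' edit calls are Bernoulli draws with the same step editing model as
#' [simulate_site_counts()] (SNP positions edit at `snp_fraction` in every
#' condition). A configurable fraction of reads is planted with each
#' disqualifying property — mean base quality below 20, unmapped, secondary,
#' supplementary, wrong aligned strand — to exercise the read filters.
#'
#' @inheritParams simulate_site_counts
#' @return data.frame with one row per read: read_id, isoform_id, gene_id,
#'   mapped, secondary, supplementary, quality, strand (aligned), tx_strand
#'   (annotated), edited_C, total_C, edit_positions (";"-joined 0-based
#'   genomic coordinates, empty string if none)
#' @export
simulate_long_reads <- function(reference, config = reference$config,
                                condition, replicate) {
  condition <- match.arg(condition, .conditions())
  if (replicate < 1L || replicate > config$n_replicates) {
    stop("replicate index out of range: ", replicate)
  }
  ann <- reference$annotation
  cs <- reference$c_sites
  p_site <- .site_edit_prob(reference, condition)
  p_site[cs$is_snp] <- config$snp_fraction
  p_by_pos <- setNames(p_site, paste0(cs$gene_id, ":", cs$pos0))
  txc <- .tx_c_positions(reference)

  tab_seed <- derive_seed(config$seed, condition, replicate) + 7L
  withr::with_seed(tab_seed, {
    rows <- list()
    rid <- 0L
    for (ti in seq_len(nrow(ann$transcripts))) {
      tid <- ann$transcripts$transcript_id[ti]
      gid <- ann$transcripts$gene_id[ti]
      tstrand <- ann$genes$strand[ann$genes$gene_id == gid]
      pos <- txc[[tid]]
      n_c <- length(pos)
      n_reads <- rpois(1L, config$reads_per_isoform)
      if (n_reads == 0L) next
      p <- if (n_c) unname(p_by_pos[paste0(gid, ":", pos)]) else numeric(0)

      edited <- if (n_c) {
        matrix(runif(n_reads * n_c) < rep(p, each = n_reads),
               nrow = n_reads, ncol = n_c)
      } else {
        matrix(FALSE, nrow = n_reads, ncol = 0L)
      }
      edit_pos <- apply(edited, 1L, function(e) paste(pos[e], collapse = ";"))
      edited_c <- as.integer(rowSums(edited))

      cf <- config$contaminant_fraction
      lowq <- runif(n_reads) < cf
      unmapped <- runif(n_reads) < cf
      secondary <- runif(n_reads) < cf
      supplementary <- runif(n_reads) < cf
      wrong_strand <- runif(n_reads) < cf
      quality <- ifelse(lowq, runif(n_reads, 10, 19.5), runif(n_reads, 25, 40))
      strand <- ifelse(wrong_strand, chartr("+-", "-+", tstrand), tstrand)

      rows[[tid]] <- data.frame(
        read_id = sprintf("%s_r%s_%05d", tid, replicate, rid + seq_len(n_reads)),
        isoform_id = tid, gene_id = gid,
        mapped = !unmapped, secondary = secondary,
        supplementary = supplementary, quality = round(quality, 1),
        strand = strand, tx_strand = tstrand,
        edited_C = edited_c, total_C = n_c,
        edit_positions = edit_pos,
        stringsAsFactors = FALSE
      )
      rid <- rid + n_reads
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  })
}
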
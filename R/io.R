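#' Construct a feature annotation
#'
#' Container for transcript models decomposed into stranded segments.
#' `features` carries one row per segment with `type` in `five_utr`, `cds`,
#' `three_utr`, `intron`; coordinates are 0-based half-open; strand is
#' mandatory everywhere.
#'
#' @param genes data.frame: gene_id, chrom, start0, end0, strand
#' @param transcripts data.frame: transcript_id, gene_id, primary
#' @param features data.frame: chrom, start0, end0, strand, gene_id,
#'   transcript_id, type
#' @return an object of class `feature_annotation`
#' @export
feature_annotation <- function(genes, transcripts, features) {
  stopifnot(
    all(c("gene_id", "chrom", "start0", "end0", "strand") %in% names(genes)),
    all(c("transcript_id", "gene_id") %in% names(transcripts)),
    all(c("chrom", "start0", "end0", "strand", "gene_id", "transcript_id",
          "type") %in% names(features))
  )
  if (any(!genes$strand %in% c("+", "-")) ||
      any(!features$strand %in% c("+", "-"))) {
    stop("unstranded interval records are not allowed")
  }
  if (!"primary" %in% names(transcripts)) transcripts$primary <- TRUE
  structure(list(genes = genes, transcripts = transcripts, features = features),
            class = "feature_annotation")
}

#' @export
print.feature_annotation <- function(x, ...) {
  cat(sprintf("feature_annotation: %d genes, %d transcripts, %d segments\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$features)))
  invisible(x)
}

#' Segments of the primary transcript of every gene
#'
#' The gene-level decomposition used for cluster windows, background-rate
#' classes and cluster shuffling.
#'
#' @param annotation a `feature_annotation`
#' @return feature data.frame (one row per exon/intron/UTR segment)
#' @export
gene_features <- function(annotation) {
  prim <- annotation$transcripts$transcript_id[annotation$transcripts$primary]
  fx <- annotation$features[annotation$features$transcript_id %in% prim, ]
  rownames(fx) <- NULL
  fx
}

## ---------------------------------------------------------------- GTF ----

#' Write a feature annotation as GTF (1-based inclusive)
#'
#' Emits gene, transcript and exon rows plus UTR rows for terminal UTR exons;
#' introns are not written (they are re-derived as inter-exon gaps on read).
#'
#' @param annotation a `feature_annotation`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gtf <- function(annotation, path) {
  rows <- list()
  g <- annotation$genes
  rows$gene <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start0 + 1L, g$end0), g$strand,
    type = "gene", gene_id = g$gene_id, transcript_id = NA_character_
  )
  tx <- annotation$transcripts
  fx <- annotation$features
  tx_rows <- lapply(seq_len(nrow(tx)), function(i) {
    f <- fx[fx$transcript_id == tx$transcript_id[i], ]
    ex <- f[f$type %in% .exonic_types(), ]
    gr_tx <- GenomicRanges::GRanges(
      ex$chrom[1], IRanges::IRanges(min(ex$start0) + 1L, max(ex$end0)),
      ex$strand[1], type = "transcript", gene_id = tx$gene_id[i],
      transcript_id = tx$transcript_id[i]
    )
    gr_ex <- GenomicRanges::GRanges(
      ex$chrom, IRanges::IRanges(ex$start0 + 1L, ex$end0), ex$strand,
      type = "exon", gene_id = tx$gene_id[i],
      transcript_id = tx$transcript_id[i]
    )
    utr <- ex[ex$type %in% c("five_utr", "three_utr"), ]
    gr_utr <- if (nrow(utr)) {
      GenomicRanges::GRanges(
        utr$chrom, IRanges::IRanges(utr$start0 + 1L, utr$end0), utr$strand,
        type = "UTR", gene_id = tx$gene_id[i],
        transcript_id = tx$transcript_id[i]
      )
    } else NULL
    suppressWarnings(do.call(c, Filter(Negate(is.null),
                                       list(gr_tx, gr_ex, gr_utr))))
  })
  gr <- suppressWarnings(do.call(c, c(rows, tx_rows)))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a GTF annotation into a feature annotation
#'
#' Converts 1-based inclusive GTF coordinates to internal 0-based half-open,
#' derives introns as inter-exon gaps, and labels terminal UTR exons (as
#' flagged by UTR rows) as `five_utr`/`three_utr` in transcription order;
#' remaining exons become `cds`.
#'
#' @param path GTF file
#' @return a `feature_annotation`
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (any(df$strand == "*")) stop("GTF contains unstranded records: ", path)
  df$start0 <- df$start - 1L
  df$end0 <- df$end
  df$chrom <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)

  ex <- df[df$type == "exon", ]
  if (!nrow(ex)) stop("GTF contains no exon records: ", path)
  utr <- df[df$type == "UTR", ]
  tx_ids <- unique(ex$transcript_id)

  feats <- list()
  transcripts <- list()
  for (tid in tx_ids) {
    e <- ex[ex$transcript_id == tid, ]
    e <- e[order(e$start0), ]
    gid <- e$gene_id[1]
    strand <- e$strand[1]
    n <- nrow(e)
    u <- utr[!is.na(utr$transcript_id) & utr$transcript_id == tid, ]
    is_utr <- e$start0 %in% u$start0 & e$end0 %in% u$end0
    tx_order <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    type <- rep("cds", n)
    if (n >= 2L) {
      if (is_utr[tx_order[1]]) type[tx_order[1]] <- "five_utr"
      if (is_utr[tx_order[n]]) type[tx_order[n]] <- "three_utr"
    }
    seg <- data.frame(
      chrom = e$chrom, start0 = e$start0, end0 = e$end0, strand = strand,
      gene_id = gid, transcript_id = tid, type = type,
      stringsAsFactors = FALSE
    )
    if (n >= 2L) {
      seg <- rbind(seg, data.frame(
        chrom = e$chrom[1], start0 = e$end0[-n], end0 = e$start0[-1],
        strand = strand, gene_id = gid, transcript_id = tid, type = "intron",
        stringsAsFactors = FALSE
      ))
    }
    seg <- seg[order(seg$start0), ]
    feats[[tid]] <- seg
    transcripts[[tid]] <- data.frame(
      transcript_id = tid, gene_id = gid, stringsAsFactors = FALSE
    )
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  transcripts <- do.call(rbind, transcripts)
  rownames(transcripts) <- NULL
  ## first transcript listed per gene is the primary one
  transcripts$primary <- !duplicated(transcripts$gene_id)

  gdf <- df[df$type == "gene", ]
  genes <- if (nrow(gdf)) {
    data.frame(gene_id = gdf$gene_id, chrom = gdf$chrom, start0 = gdf$start0,
               end0 = gdf$end0, strand = gdf$strand, stringsAsFactors = FALSE)
  } else {
    agg <- do.call(rbind, lapply(split(features, features$gene_id), function(f) {
      data.frame(gene_id = f$gene_id[1], chrom = f$chrom[1],
                 start0 = min(f$start0), end0 = max(f$end0),
                 strand = f$strand[1], stringsAsFactors = FALSE)
    }))
    rownames(agg) <- NULL
    agg
  }
  genes <- genes[order(genes$start0), ]
  rownames(genes) <- NULL
  feature_annotation(genes, transcripts, features)
}

## ---------------------------------------------------------------- BED ----

#' Read a BED6(+) file (0-based half-open)
#'
#' @param path BED file; at least 6 columns, strand required
#' @param extra_cols optional names for columns beyond the sixth
#' @return data.frame: chrom, start0, end0, name, score, strand (+ extras)
#' @export
read_bed <- function(path, extra_cols = NULL) {
  if (!file.exists(path)) stop("no such BED file: ", path)
  empty <- data.frame(chrom = character(), start0 = integer(),
                      end0 = integer(), name = character(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE)
  for (cc in extra_cols) empty[[cc]] <- numeric()
  if (file.size(path) == 0L) return(empty)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 6L) stop("BED file must have >= 6 columns (strand required): ", path)
  names(df)[1:6] <- c("chrom", "start0", "end0", "name", "score", "strand")
  if (!is.null(extra_cols) && ncol(df) >= 6L + length(extra_cols)) {
    names(df)[6L + seq_along(extra_cols)] <- extra_cols
  }
  if (any(!df$strand %in% c("+", "-"))) {
    stop("BED file contains records without a valid strand: ", path)
  }
  df
}

#' Write intervals as BED6(+)
#'
#' Intervals must carry chrom/start0/end0/strand; `name` and `score` are
#' filled in when absent (for clusters, score = -log10(q)). Any columns named
#' in `extra_cols` are appended after the sixth column.
#'
#' @param intervals interval data.frame
#' @param path output file
#' @param extra_cols character vector of extra column names to append
#' @return `path`, invisibly
#' @export
write_bed <- function(intervals, path, extra_cols = NULL) {
  if (any(!intervals$strand %in% c("+", "-"))) {
    stop("refusing to write unstranded intervals")
  }
  name <- intervals$name %||% sprintf("iv%05d", seq_len(nrow(intervals)))
  score <- intervals$score %||% rep(0, nrow(intervals))
  out <- data.frame(intervals$chrom, intervals$start0, intervals$end0,
                    name, score, intervals$strand, stringsAsFactors = FALSE)
  for (cc in extra_cols) out[[cc]] <- intervals[[cc]]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------- TSV ----

#' Read/write per-site count tables (chrom, pos0, strand, ref_count, alt_count)
#' @param path TSV file
#' @return data.frame of per-site counts
#' @export
read_site_counts <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos0", "strand", "ref_count", "alt_count")
  if (!all(need %in% names(df))) {
    stop("site count table must have columns ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_site_counts
#' @param counts per-site count data.frame
#' @export
write_site_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write long-read tables (schema of [simulate_long_reads()])
#' @param path TSV file
#' @return data.frame of reads
#' @export
read_long_reads <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = NA, na.strings = "NA")
  df$edit_positions[is.na(df$edit_positions)] <- ""
  df
}

#' @rdname read_long_reads
#' @param reads read data.frame
#' @export
write_long_reads <- function(reads, path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ------------------------------------------------------------- bundle ----

#' Write a complete synthetic fixture bundle to disk
#'
#' Writes the genome FASTA, annotation GTF, truth BEDs (bound motifs, SNPs),
#' per-condition per-replicate site-count TSVs and (optionally) long-read
#' TSVs. Everything round-trips through this package's readers.
#'
#' @param reference a `sim_reference`
#' @param dir output directory (created if needed)
#' @param conditions conditions to simulate site counts for
#' @param long_reads if `TRUE`, also write long-read tables per condition and
#'   replicate (buffer-only excluded: the long-read protocol has no
#'   buffer-only arm)
#' @return named list of file paths, invisibly
#' @export
write_fixture_bundle <- function(reference, dir,
                                 conditions = .conditions(),
                                 long_reads = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- reference$config
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gtf"),
    motifs = file.path(dir, "truth_motifs.bed"),
    snps = file.path(dir, "truth_snps.bed")
  )
  Biostrings::writeXStringSet(reference$genome, paths$genome)
  write_gtf(reference$annotation, paths$annotation)
  write_bed(reference$truth$motifs, paths$motifs)
  write_bed(reference$truth$snps, paths$snps)
  for (cond in conditions) {
    for (r in seq_len(cfg$n_replicates)) {
      key <- sprintf("sites_%s_rep%d", cond, r)
      paths[[key]] <- file.path(dir, paste0(key, ".tsv"))
      write_site_counts(simulate_site_counts(reference, cfg, cond, r),
                        paths[[key]])
    }
  }
  if (long_reads) {
    for (cond in setdiff(conditions, "buffer_only")) {
      for (r in seq_len(cfg$n_replicates)) {
        key <- sprintf("reads_%s_rep%d", cond, r)
        paths[[key]] <- file.path(dir, paste0(key, ".tsv"))
        write_long_reads(simulate_long_reads(reference, cfg, cond, r),
                         paths[[key]])
      }
    }
  }
  invisible(paths)
}
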
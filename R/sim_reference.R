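#' Feature types treated as exonic
#' @noRd
.exonic_types <- function() c("five_utr", "cds", "three_utr")

#' Generate a synthetic stranded reference with planted motifs and SNPs
#'
#' Builds a toy genome (one chromosome), a transcript annotation decomposed
#' into stranded 5'UTR/CDS/3'UTR/intron segments, and a ground truth: exactly
#' `n_bound_motifs` sense-strand motif instances written into transcribed
#' regions, plus SNP positions at transcribed sense-C sites. Genes are
#' non-overlapping and alternate between the two strands. Decoy (unbound)
#' motif occurrences arise naturally from the random background base
#' composition.
#'
#' @param config a [sim_config()]
#' @return an object of class `sim_reference`: a list with elements
#'   `genome` (a [Biostrings::DNAStringSet]), `annotation`
#'   (a `feature_annotation`, see [read_gtf()]), `truth` (list with `motifs`
#'   and `snps` interval data.frames), `c_sites` (per transcribed sense-C
#'   position: chrom, pos0, strand, gene_id, type, dist_motif) and `config`.
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, .generate_reference_impl(config))
}

#' @noRd
.generate_reference_impl <- function(cfg) {
  chrom <- "chr1"
  motif_dna <- .motif_to_dna(cfg$motif)
  mlen <- nchar(motif_dna)

  ## ---- gene structures -------------------------------------------------
  genes <- vector("list", cfg$n_genes)
  feats <- vector("list", cfg$n_genes)
  cursor <- cfg$intergenic_gap
  for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("g%03d", i)
    strand <- if (i %% 2L == 1L) "+" else "-"
    n_ex <- .sample_range(cfg$exons_per_gene[1], cfg$exons_per_gene[2], 1L)
    elen <- .sample_range(cfg$exon_len[1], cfg$exon_len[2], n_ex)
    ilen <- if (n_ex > 1L) {
      .sample_range(cfg$intron_len[1], cfg$intron_len[2], n_ex - 1L)
    } else integer(0)

    seg_len <- integer(2L * n_ex - 1L)
    seg_len[seq(1L, 2L * n_ex - 1L, by = 2L)] <- elen
    if (n_ex > 1L) seg_len[seq(2L, 2L * n_ex - 2L, by = 2L)] <- ilen
    seg_start <- cursor + c(0L, cumsum(seg_len)[-length(seg_len)])
    seg_end <- seg_start + seg_len
    is_exon <- rep(c(TRUE, FALSE), length.out = 2L * n_ex - 1L)

    ## exon types in transcription order
    ex_idx_genomic <- which(is_exon)
    tx_order <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    ex_type <- rep("cds", n_ex)
    if (n_ex >= 2L) {
      ex_type[tx_order[1L]] <- "five_utr"
      ex_type[tx_order[n_ex]] <- "three_utr"
    }
    type <- ifelse(is_exon, NA_character_, "intron")
    type[ex_idx_genomic] <- ex_type

    feats[[i]] <- data.frame(
      chrom = chrom, start0 = seg_start, end0 = seg_end, strand = strand,
      gene_id = gid, transcript_id = paste0(gid, ".t1"), type = type,
      stringsAsFactors = FALSE
    )
    genes[[i]] <- data.frame(
      gene_id = gid, chrom = chrom, start0 = cursor,
      end0 = cursor + sum(seg_len), strand = strand,
      stringsAsFactors = FALSE
    )
    cursor <- cursor + sum(seg_len) + cfg$intergenic_gap
  }
  genes <- do.call(rbind, genes)
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  genome_len <- cursor

  ## ---- alternative isoforms via exon skipping --------------------------
  transcripts <- data.frame(
    transcript_id = paste0(genes$gene_id, ".t1"),
    gene_id = genes$gene_id, primary = TRUE, stringsAsFactors = FALSE
  )
  if (cfg$exon_skipping) {
    extra <- list()
    for (gid in genes$gene_id) {
      fx <- features[features$gene_id == gid, ]
      ex <- fx[fx$type %in% .exonic_types(), ]
      if (nrow(ex) >= 3L && runif(1) < cfg$skip_prob) {
        cds_idx <- which(ex$type == "cds")
        skip <- cds_idx[sample.int(length(cds_idx), 1L)]
        kept <- ex[-skip, ]
        kept <- kept[order(kept$start0), ]
        n <- nrow(kept)
        alt <- rbind(kept, data.frame(
          chrom = kept$chrom[1], start0 = kept$end0[-n], end0 = kept$start0[-1],
          strand = kept$strand[1], gene_id = gid,
          transcript_id = kept$transcript_id[1], type = "intron",
          stringsAsFactors = FALSE
        ))
        alt <- alt[order(alt$start0), ]
        alt$transcript_id <- paste0(gid, ".t2")
        extra[[gid]] <- alt
        transcripts <- rbind(transcripts, data.frame(
          transcript_id = paste0(gid, ".t2"), gene_id = gid, primary = FALSE,
          stringsAsFactors = FALSE
        ))
      }
    }
    if (length(extra)) features <- rbind(features, do.call(rbind, extra))
    rownames(features) <- NULL
  }

  ## ---- genome sequence --------------------------------------------------
  base <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)

  ## ---- plant bound motifs ----------------------------------------------
  prim <- features[features$transcript_id %in%
                     transcripts$transcript_id[transcripts$primary], ]
  cand <- if (cfg$motif_placement == "exonic") {
    prim[prim$type %in% .exonic_types(), ]
  } else {
    prim
  }
  cand <- cand[(cand$end0 - cand$start0) >= mlen, ]
  if (cfg$n_bound_motifs > 0L && nrow(cand) == 0L) {
    stop("motif placement infeasible: no segment can hold the motif")
  }
  motifs <- data.frame(
    chrom = character(), start0 = integer(), end0 = integer(),
    strand = character(), gene_id = character(), stringsAsFactors = FALSE
  )
  if (cfg$n_bound_motifs > 0L) {
    w <- cand$end0 - cand$start0 - mlen + 1L
    placed_start <- integer(0)
    tries <- 0L
    max_tries <- 500L * cfg$n_bound_motifs
    while (length(placed_start) < cfg$n_bound_motifs) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("motif placement infeasible: could not place ",
             cfg$n_bound_motifs, " non-overlapping motifs")
      }
      j <- sample.int(nrow(cand), 1L, prob = w)
      s <- cand$start0[j] + sample.int(w[j], 1L) - 1L
      if (any(abs(placed_start - s) < mlen)) next
      placed_start <- c(placed_start, s)
      motifs <- rbind(motifs, data.frame(
        chrom = chrom, start0 = s, end0 = s + mlen,
        strand = cand$strand[j], gene_id = cand$gene_id[j],
        stringsAsFactors = FALSE
      ))
    }
    ## write sense-strand motif into the genome
    for (k in seq_len(nrow(motifs))) {
      seq_sense <- if (motifs$strand[k] == "+") {
        motif_dna
      } else {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif_dna)))
      }
      base[(motifs$start0[k] + 1L):(motifs$end0[k])] <-
        strsplit(seq_sense, "")[[1]]
    }
    motifs <- motifs[order(motifs$start0), ]
    rownames(motifs) <- NULL
  }

  ## ---- transcribed sense-C sites ---------------------------------------
  c_sites <- .collect_c_sites(base, genes, features, transcripts)

  ## ---- SNP positions ----------------------------------------------------
  in_motif <- rep(FALSE, nrow(c_sites))
  if (nrow(motifs)) {
    hits <- GenomicRanges::findOverlaps(
      .pos_granges(c_sites$chrom, c_sites$pos0),
      .as_granges(motifs), ignore.strand = TRUE
    )
    in_motif[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  snp_pool <- which(!in_motif)
  n_snps <- min(cfg$n_snps, length(snp_pool))
  snp_idx <- if (n_snps > 0L) sort(sample(snp_pool, n_snps)) else integer(0)
  snps <- data.frame(
    chrom = c_sites$chrom[snp_idx], start0 = c_sites$pos0[snp_idx],
    end0 = c_sites$pos0[snp_idx] + 1L, strand = c_sites$strand[snp_idx],
    stringsAsFactors = FALSE
  )

  ## ---- distance to nearest same-gene motif ------------------------------
  c_sites$dist_motif <- .dist_to_motif(c_sites, motifs)
  c_sites$is_snp <- seq_len(nrow(c_sites)) %in% snp_idx

  genome <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(genome) <- chrom

  annotation <- feature_annotation(genes, transcripts, features)
  structure(
    list(genome = genome, annotation = annotation,
         truth = list(motifs = motifs, snps = snps),
         c_sites = c_sites, config = cfg),
    class = "sim_reference"
  )
}

#' Transcribed sense-C positions (genomic C on + genes, genomic G on - genes)
#' @noRd
.collect_c_sites <- function(base, genes, features, transcripts) {
  out <- vector("list", nrow(genes))
  prim <- features[features$transcript_id %in%
                     transcripts$transcript_id[transcripts$primary], ]
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    span <- (g$start0 + 1L):g$end0
    letters_g <- base[span]
    target <- if (g$strand == "+") "C" else "G"
    pos0 <- span[letters_g == target] - 1L
    if (!length(pos0)) next
    fx <- prim[prim$gene_id == g$gene_id, ]
    type <- rep(NA_character_, length(pos0))
    for (k in seq_len(nrow(fx))) {
      sel <- pos0 >= fx$start0[k] & pos0 < fx$end0[k]
      type[sel] <- fx$type[k]
    }
    out[[i]] <- data.frame(
      chrom = g$chrom, pos0 = pos0, strand = g$strand, gene_id = g$gene_id,
      type = type, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distance from a C position to the nearest base of a same-gene motif
#' @noRd
.dist_to_motif <- function(c_sites, motifs) {
  d <- rep(Inf, nrow(c_sites))
  if (!nrow(motifs)) return(d)
  for (gid in unique(motifs$gene_id)) {
    m <- motifs[motifs$gene_id == gid, ]
    idx <- which(c_sites$gene_id == gid)
    if (!length(idx)) next
    p <- c_sites$pos0[idx]
    dm <- rep(Inf, length(idx))
    for (k in seq_len(nrow(m))) {
      dk <- pmax(0, pmax(m$start0[k] - p, p - (m$end0[k] - 1L)))
      dm <- pmin(dm, dk)
    }
    d[idx] <- dm
  }
  d
}
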
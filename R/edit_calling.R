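#' Pileup per-site C-to-U counts from SAM alignments
#'
#' Counts only positions that are C on the annotated gene's sense strand
#' (genomic C for + genes, genomic G for - genes). A mismatch is counted as
#' edited only for C>T on + genes and G>A on - genes; other mismatches are
#' ignored. Reads aligned to the strand inconsistent with the gene are
#' excluded. Positions with no C/T (resp. G/A) evidence are not emitted.
#'
#' @param sam_path path to a SAM (or BAM) file
#' @param genome a [Biostrings::DNAStringSet] (the reference the reads were
#'   aligned to)
#' @param annotation a `feature_annotation` supplying gene strand
#' @return per-site count data.frame (chrom, pos0, strand, ref_count,
#'   alt_count)
#' @export
pileup_counts <- function(sam_path, genome, annotation) {
  bam <- if (grepl("\\.bam$", sam_path)) {
    sam_path
  } else {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(sam_path, destination = dest,
                     overwrite = TRUE, indexDestination = TRUE)
  }
  pp <- Rsamtools::PileupParam(
    max_depth = 100000L, min_base_quality = 0L, min_mapq = 0L,
    min_nucleotide_depth = 1L, distinguish_strands = TRUE,
    distinguish_nucleotides = TRUE, include_deletions = FALSE,
    include_insertions = FALSE
  )
  p <- Rsamtools::pileup(bam, pileupParam = pp)
  if (!nrow(p)) {
    return(data.frame(chrom = character(), pos0 = integer(),
                      strand = character(), ref_count = integer(),
                      alt_count = integer(), stringsAsFactors = FALSE))
  }
  p$chrom <- as.character(p$seqnames)
  p$strand <- as.character(p$strand)
  p$nucleotide <- as.character(p$nucleotide)

  out <- list()
  for (i in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[i, ]
    if (is.na(g$strand) || !g$strand %in% c("+", "-")) {
      warning("gene without strand skipped: ", g$gene_id)
      next
    }
    if (!g$chrom %in% names(genome)) {
      stop("gene ", g$gene_id, " lies on a chromosome absent from the genome")
    }
    pg <- p[p$chrom == g$chrom & p$pos > g$start0 & p$pos <= g$end0 &
              p$strand == g$strand, ]
    if (!nrow(pg)) next
    if (max(pg$pos) > length(genome[[g$chrom]])) {
      stop("alignment position outside the genome on ", g$chrom)
    }
    ref_base <- if (g$strand == "+") "C" else "G"
    alt_base <- if (g$strand == "+") "T" else "A"
    gseq <- strsplit(as.character(
      Biostrings::subseq(genome[[g$chrom]], g$start0 + 1L, g$end0)), "")[[1]]
    pg$refnt <- gseq[pg$pos - g$start0]
    pg <- pg[pg$refnt == ref_base & pg$nucleotide %in% c(ref_base, alt_base), ]
    if (!nrow(pg)) next
    agg <- lapply(split(pg, pg$pos), function(x) {
      data.frame(
        chrom = g$chrom, pos0 = x$pos[1] - 1L, strand = g$strand,
        ref_count = sum(x$count[x$nucleotide == ref_base]),
        alt_count = sum(x$count[x$nucleotide == alt_base]),
        stringsAsFactors = FALSE
      )
    })
    out[[g$gene_id]] <- do.call(rbind, agg)
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(chrom = character(), pos0 = integer(), strand = character(),
               ref_count = integer(), alt_count = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res[order(res$chrom, res$pos0), ]
}

#' Confidence score for a candidate edit site
#'
#' Posterior probability that the site's true edit rate exceeds the
#' background rate, under a Jeffreys Beta(1/2, 1/2) prior on the rate with a
#' binomial likelihood:
#' `score = P(p > p_bg | alt, ref) = 1 - pbeta(p_bg, alt + 1/2, ref + 1/2)`.
#' Monotone non-decreasing in `alt` at fixed `ref` and non-increasing in
#' `ref` at fixed `alt`. This coverage-aware exceedance score lies in [0, 1]
#' and respects the "discard below 0.5" filter semantics.
#'
#' @param alt_count,ref_count edited / reference read counts (vectorised)
#' @param p_bg background per-read edit probability, in (0, 1)
#' @return scores in [0, 1]
#' @export
score_edit_site <- function(alt_count, ref_count, p_bg) {
  if (length(p_bg) != 1L || !is.finite(p_bg) || p_bg <= 0 || p_bg >= 1) {
    stop("p_bg must be a single value in (0, 1)")
  }
  if (any(alt_count + ref_count <= 0)) {
    stop("score requires alt_count + ref_count > 0")
  }
  pbeta(p_bg, alt_count + 0.5, ref_count + 0.5, lower.tail = FALSE)
}

#' Call candidate edit sites from a per-site count table
#'
#' A candidate edit site is a covered sense-C position with at least one
#' edited read. Adds the edit fraction and the confidence score against the
#' supplied background rate.
#'
#' @param counts per-site count table (chrom, pos0, strand, ref_count,
#'   alt_count)
#' @param p_bg background per-read edit probability used for scoring
#' @return data.frame of scored candidate edit sites (adds edit_fraction,
#'   score)
#' @export
call_edit_sites <- function(counts, p_bg) {
  keep <- counts$alt_count >= 1L
  sites <- counts[keep, , drop = FALSE]
  sites$edit_fraction <- sites$alt_count / (sites$alt_count + sites$ref_count)
  sites$score <- score_edit_site(sites$alt_count, sites$ref_count, p_bg)
  rownames(sites) <- NULL
  sites
}

#' Filter scored edit sites on confidence, edit fraction and known SNPs
#'
#' Retains sites with `score > score_min` and `edit_fraction < fraction_max`
#' (both comparisons exclusive) whose position is not in `snp_positions`.
#' High apparent fractions typically represent SNPs rather than editing.
#'
#' @param sites scored edit sites from [call_edit_sites()]
#' @param snp_positions interval data.frame of known SNPs (chrom, start0,
#'   end0, strand) or `NULL`
#' @param score_min confidence threshold (exclusive), default 0.5
#' @param fraction_max edit-fraction ceiling (exclusive), default 0.8
#' @return filtered site data.frame
#' @export
filter_edit_sites <- function(sites, snp_positions = NULL,
                              score_min = 0.5, fraction_max = 0.8) {
  keep <- sites$score > score_min & sites$edit_fraction < fraction_max
  if (!is.null(snp_positions) && nrow(snp_positions)) {
    hits <- GenomicRanges::findOverlaps(
      .pos_granges(sites$chrom, sites$pos0),
      .as_granges(snp_positions), ignore.strand = TRUE
    )
    keep[unique(S4Vectors::queryHits(hits))] <- FALSE
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global edit fraction of one or more count tables
#'
#' Pooled `sum(alt) / sum(alt + ref)`; with buffer-only control tables this
#' is the default background rate for scoring.
#'
#' @param counts a count table or list of count tables
#' @return a single fraction
#' @export
global_edit_fraction <- function(counts) {
  if (is.data.frame(counts)) counts <- list(counts)
  alt <- sum(vapply(counts, function(x) sum(x$alt_count), numeric(1)))
  tot <- sum(vapply(counts, function(x) sum(x$alt_count + x$ref_count),
                    numeric(1)))
  if (tot == 0) stop("no covered positions")
  alt / tot
}
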
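#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-table RNG seed from the master seed
#'
#' Stable integer hash of (seed, condition, replicate) so that every simulated
#' table is reproducible in isolation. Result always lies in [1, 2^31 - 2].
#'
#' @param seed master integer seed
#' @param condition one of `"case"`, `"enzyme_only"`, `"buffer_only"`
#' @param replicate 1-based replicate index
#' @return an integer seed
#' @export
derive_seed <- function(seed, condition, replicate) {
  cond <- match(condition, c("case", "enzyme_only", "buffer_only"))
  if (is.na(cond)) stop("unknown condition: ", condition)
  x <- (as.numeric(seed) * 100003 + cond * 10007 + as.numeric(replicate) * 101) %%
    2147483629
  as.integer(x) + 1L
}

.conditions <- function() c("case", "enzyme_only", "buffer_only")

#' Convert an interval data.frame (0-based half-open) to GRanges
#' @noRd
.as_granges <- function(df) {
  stopifnot(all(c("chrom", "start0", "end0", "strand") %in% names(df)))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start0 + 1L, end = df$end0),
    strand = df$strand
  )
}

#' Positions (0-based) to width-1 GRanges
#' @noRd
.pos_granges <- function(chrom, pos0, strand = "*") {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos0 + 1L, width = 1L),
    strand = strand
  )
}

#' Same-strand >= 1 nt overlap hits between two interval data.frames
#' @noRd
.overlap_hits <- function(a, b) {
  suppressWarnings(
    GenomicRanges::findOverlaps(.as_granges(a), .as_granges(b),
                                ignore.strand = FALSE)
  )
}

#' RNA motif to DNA sense-strand pattern
#' @noRd
.motif_to_dna <- function(motif) {
  motif <- toupper(motif)
  if (!grepl("^[ACGU]+$", motif)) {
    stop("motif must be an RNA string over {A,C,G,U}: ", motif)
  }
  chartr("U", "T", motif)
}

#' Empty cluster data.frame with the canonical columns
#' @noRd
.empty_clusters <- function() {
  data.frame(
    chrom = character(), start0 = integer(), end0 = integer(),
    strand = character(), n_edit_sites = integer(),
    p_value = numeric(), q_value = numeric(), score = numeric(),
    stringsAsFactors = FALSE
  )
}

#' Uniform integer draws from [lo, hi], safe for lo == hi
#' @noRd
.sample_range <- function(lo, hi, n) {
  as.integer(lo) + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

#' Midpoint (0-based, floor) of half-open intervals
#' @noRd
.midpoint <- function(start0, end0) {
  as.integer(floor((as.numeric(start0) + as.numeric(end0) - 1) / 2))
}
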
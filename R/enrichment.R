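#' Scan annotated genes for sense-strand motif occurrences
#'
#' Reports every occurrence of the DNA equivalent of an RNA k-mer on the
#' sense strand of annotated genes: direct matches within + genes and
#' reverse-complement matches within - genes. Occurrences outside annotated
#' genes are ignored; hits take the strand of their host gene.
#'
#' @param genome a [Biostrings::DNAStringSet]
#' @param annotation a `feature_annotation`
#' @param motif RNA k-mer over {A,C,G,U}
#' @return data.frame of hits: chrom, start0, end0, strand, gene_id
#' @export
scan_motif <- function(genome, annotation, motif) {
  pat <- Biostrings::DNAString(.motif_to_dna(motif))
  rc <- Biostrings::reverseComplement(pat)
  hits <- list()
  for (chrom in names(genome)) {
    fwd <- Biostrings::matchPattern(pat, genome[[chrom]])
    rev <- Biostrings::matchPattern(rc, genome[[chrom]])
    hits[[chrom]] <- rbind(
      data.frame(chrom = chrom, start0 = BiocGenerics::start(fwd) - 1L,
                 end0 = BiocGenerics::end(fwd), strand = "+",
                 stringsAsFactors = FALSE),
      data.frame(chrom = chrom, start0 = BiocGenerics::start(rev) - 1L,
                 end0 = BiocGenerics::end(rev), strand = "-",
                 stringsAsFactors = FALSE)
    )
  }
  occ <- do.call(rbind, hits)
  if (!nrow(occ)) {
    return(data.frame(chrom = character(), start0 = integer(),
                      end0 = integer(), strand = character(),
                      gene_id = character(), stringsAsFactors = FALSE))
  }
  genes <- annotation$genes
  ov <- GenomicRanges::findOverlaps(.as_granges(occ), .as_granges(genes),
                                    ignore.strand = FALSE,
                                    type = "within")
  res <- occ[S4Vectors::queryHits(ov), , drop = FALSE]
  res$gene_id <- genes$gene_id[S4Vectors::subjectHits(ov)]
  res <- res[order(res$chrom, res$start0), ]
  rownames(res) <- NULL
  res
}

#' Fraction of clusters containing a motif hit
#'
#' A cluster "contains" a motif when the hit span overlaps the cluster
#' interval by at least 1 nt on the same strand.
#'
#' @param clusters cluster data.frame
#' @param hits motif hits (or any stranded intervals)
#' @return fraction in [0, 1]
#' @export
motif_fraction <- function(clusters, hits) {
  if (!nrow(clusters)) stop("motif fraction is undefined for an empty cluster set")
  if (!nrow(hits)) return(0)
  ov <- .overlap_hits(clusters, hits)
  length(unique(S4Vectors::queryHits(ov))) / nrow(clusters)
}

#' Fraction of clusters overlapping a reference peak set
#'
#' Same-strand >= 1 nt overlap with any peak (e.g. eCLIP IDR peaks).
#'
#' @param clusters cluster data.frame
#' @param peaks stranded peak intervals (BED6-like data.frame)
#' @return fraction in [0, 1]
#' @export
overlap_fraction <- function(clusters, peaks) {
  if (!nrow(clusters)) stop("overlap fraction is undefined for an empty cluster set")
  if (any(!peaks$strand %in% c("+", "-"))) stop("peaks must be stranded")
  if (!nrow(peaks)) return(0)
  ov <- .overlap_hits(clusters, peaks)
  length(unique(S4Vectors::queryHits(ov))) / nrow(clusters)
}

#' Shuffle clusters within their host exon or intron
#'
#' The host feature of a cluster is the exon or intron (UTRs counted as
#' exonic) of the primary transcript containing the cluster midpoint. Each
#' permutation redraws every cluster start uniformly so the length-preserved
#' cluster fits inside its host feature; clusters longer than the host are
#' clamped to the feature span. Strand and length are always preserved.
#'
#' @param clusters cluster data.frame
#' @param annotation a `feature_annotation`
#' @param n_perm number of permutations (default 20)
#' @param seed integer seed
#' @return list of `n_perm` shuffled cluster data.frames
#' @export
shuffle_clusters <- function(clusters, annotation, n_perm = 20L, seed = 1L) {
  if (!nrow(clusters)) stop("cannot shuffle an empty cluster set")
  fx <- gene_features(annotation)
  mid <- .midpoint(clusters$start0, clusters$end0)
  ov <- GenomicRanges::findOverlaps(
    .pos_granges(clusters$chrom, mid, clusters$strand),
    .as_granges(fx), ignore.strand = FALSE, select = "first"
  )
  if (anyNA(ov)) {
    bad <- which(is.na(ov))[1]
    stop(sprintf("cluster %s:%d-%d(%s) midpoint lies outside any feature",
                 clusters$chrom[bad], clusters$start0[bad],
                 clusters$end0[bad], clusters$strand[bad]))
  }
  host <- fx[ov, , drop = FALSE]
  len <- clusters$end0 - clusters$start0
  flen <- host$end0 - host$start0
  clamped <- len >= flen

  withr::with_seed(seed, {
    lapply(seq_len(n_perm), function(i) {
      out <- clusters
      free <- !clamped
      n_off <- flen - len + 1L
      new_start <- host$start0
      if (any(free)) {
        u <- vapply(n_off[free], function(m) sample.int(m, 1L), integer(1))
        new_start[free] <- host$start0[free] + u - 1L
      }
      out$start0 <- ifelse(clamped, host$start0, new_start)
      out$end0 <- ifelse(clamped, host$end0, out$start0 + len)
      out
    })
  })
}

#' Summarise a permutation enrichment test
#'
#' `z = (observed - mean(perm)) / sd(perm)` with the sample (n-1) standard
#' deviation; `enrichment = observed / mean(perm)`. Degenerate permutations
#' (zero spread) yield `z = NA` with a message; a zero permuted mean with a
#' positive observation yields infinite enrichment, also logged.
#'
#' @param observed_fraction observed fraction in [0, 1]
#' @param permuted_fractions numeric vector of permuted fractions (>= 2)
#' @param n_perm,seed bookkeeping fields stored in the summary
#' @return list of class `permutation_summary`: observed_fraction,
#'   permuted_fractions, z_score, enrichment, n_perm, seed
#' @export
permutation_enrichment <- function(observed_fraction, permuted_fractions,
                                   n_perm = length(permuted_fractions),
                                   seed = NA_integer_) {
  if (length(permuted_fractions) < 2L) {
    stop("at least 2 permuted values are required")
  }
  m <- mean(permuted_fractions)
  s <- sd(permuted_fractions)
  z <- if (s > 0) (observed_fraction - m) / s else {
    message("permutation_enrichment: permuted spread is zero, z undefined")
    NA_real_
  }
  enr <- if (m > 0) observed_fraction / m else if (observed_fraction > 0) {
    message("permutation_enrichment: permuted mean is zero, enrichment infinite")
    Inf
  } else 1
  structure(list(observed_fraction = observed_fraction,
                 permuted_fractions = permuted_fractions,
                 z_score = z, enrichment = enr,
                 n_perm = n_perm, seed = seed),
            class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf(
    "permutation_summary: observed %.4f, permuted %.4f +/- %.4f (n=%d), z=%.2f, enrichment=%.2f\n",
    x$observed_fraction, mean(x$permuted_fractions),
    sd(x$permuted_fractions), x$n_perm, x$z_score, x$enrichment))
  invisible(x)
}

#' Motif enrichment of a cluster set against within-feature shuffles
#'
#' Convenience wrapper: observed [motif_fraction()] versus per-permutation
#' fractions of [shuffle_clusters()] sets, summarised by
#' [permutation_enrichment()].
#'
#' @param clusters cluster data.frame
#' @param hits motif hits (or peaks)
#' @param annotation a `feature_annotation`
#' @param n_perm permutations (default 20)
#' @param seed integer seed
#' @return a `permutation_summary`
#' @export
motif_enrichment <- function(clusters, hits, annotation, n_perm = 20L,
                             seed = 1L) {
  obs <- motif_fraction(clusters, hits)
  perms <- shuffle_clusters(clusters, annotation, n_perm = n_perm, seed = seed)
  pf <- vapply(perms, function(p) {
    if (!nrow(hits)) 0 else motif_fraction(p, hits)
  }, numeric(1))
  permutation_enrichment(obs, pf, n_perm = n_perm, seed = seed)
}

#' Signed distance from clusters to their nearest target
#'
#' Midpoint-to-midpoint genomic distance to the nearest target (motif hit or
#' peak), sign flipped on the - strand so that positive means downstream in
#' transcript orientation. The minimum-|d| target is chosen; ties break
#' toward the negative (upstream) side.
#'
#' @param clusters cluster data.frame
#' @param targets stranded target intervals (non-empty)
#' @return numeric vector of signed distances (nt), one per cluster; NA when
#'   no same-chromosome target exists
#' @export
nearest_feature_distance <- function(clusters, targets) {
  if (!nrow(targets)) stop("target set must be non-empty")
  cm <- .midpoint(clusters$start0, clusters$end0)
  tm <- .midpoint(targets$start0, targets$end0)
  res <- rep(NA_real_, nrow(clusters))
  for (chrom in unique(clusters$chrom)) {
    ti <- which(targets$chrom == chrom)
    ci <- which(clusters$chrom == chrom)
    if (!length(ti)) next
    t_sorted <- sort(tm[ti])
    lo <- findInterval(cm[ci], t_sorted)
    cand_lo <- t_sorted[pmax(lo, 1L)]
    cand_hi <- t_sorted[pmin(lo + 1L, length(t_sorted))]
    d_lo <- cand_lo - cm[ci]
    d_hi <- cand_hi - cm[ci]
    flip <- clusters$strand[ci] == "-"
    d_lo[flip] <- -d_lo[flip]
    d_hi[flip] <- -d_hi[flip]
    ## minimum-|d|, ties broken toward the upstream (negative) side
    pick_lo <- abs(d_lo) < abs(d_hi) |
      (abs(d_lo) == abs(d_hi) & d_lo <= d_hi)
    res[ci] <- ifelse(pick_lo, d_lo, d_hi)
  }
  res
}

#' Editing-radius estimate from case and control distance samples
#'
#' Builds empirical CDFs of |distance| on the integer grid [0, grid_max]
#' (each sample restricted to the grid) and locates where the case excess
#' over the control stops accumulating: the smallest d at which the CDF
#' difference is within `epsilon` of its maximum over the grid. Identical
#' samples give 0; a case sample wholly within r of its targets against a
#' diffuse control gives approximately r.
#'
#' @param case_distances,control_distances signed or absolute distance
#'   samples (nt), non-empty
#' @param grid_max grid upper bound in nt (default 1000)
#' @param epsilon convergence tolerance on the CDF difference (default 0.02)
#' @return radius estimate in nt (`grid_max` when the excess never converges
#'   inside the grid)
#' @export
edit_radius <- function(case_distances, control_distances,
                        grid_max = 1000L, epsilon = 0.02) {
  stopifnot(length(case_distances) > 0, length(control_distances) > 0)
  grid <- 0:grid_max
  cdf <- function(x) {
    x <- floor(abs(x[is.finite(x)]))
    x <- x[x <= grid_max]
    if (!length(x)) return(rep(0, length(grid)))
    ecdf_x <- cumsum(tabulate(x + 1L, nbins = grid_max + 1L))
    ecdf_x / length(x)
  }
  d <- cdf(case_distances) - cdf(control_distances)
  dmax <- max(d)
  idx <- which(d >= dmax - epsilon)
  if (!length(idx)) return(as.integer(grid_max))
  grid[idx[1L]]
}
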
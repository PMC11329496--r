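#' Upper tail of the Poisson distribution
#'
#' `P(X >= k)` for `X ~ Poisson(lam)`, computed through the stable survival
#' function (never as `1 - CDF`).
#'
#' @param k observed count(s), non-negative integers
#' @param lam expected count(s), strictly positive
#' @return tail probabilities
#' @export
poisson_tail <- function(k, lam) {
  if (any(lam <= 0)) stop("lam must be > 0")
  if (any(k < 0) || any(k != floor(k))) stop("k must be a non-negative integer")
  ppois(k - 1, lam, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up adjustment with cumulative-minimum enforcement and
#' clipping at 1; permuting the input permutes the output identically.
#'
#' @param p_values p-values in [0, 1]
#' @return q-values of the same length and order
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Cluster-calling model parameters
#'
#' @param window_len window length in nt (default 50)
#' @param window_step window step in nt (default 10; must be <= window_len)
#' @param fdr_threshold BH-FDR threshold on windows (default 0.1)
#' @param merge_distance maximal gap (nt) between significant same-strand
#'   windows that are merged into one cluster (default 15)
#' @param p_bg named per-region-class edit-site rates (per covered C), as
#'   returned by [estimate_background_rate()]
#' @return list of class `cluster_model`
#' @export
cluster_model <- function(window_len = 50L, window_step = 10L,
                          fdr_threshold = 0.1, merge_distance = 15L,
                          p_bg) {
  stopifnot(window_step <= window_len, window_step >= 1L,
            merge_distance >= 0L,
            fdr_threshold > 0, fdr_threshold < 1)
  structure(list(window_len = as.integer(window_len),
                 window_step = as.integer(window_step),
                 fdr_threshold = fdr_threshold,
                 merge_distance = as.integer(merge_distance),
                 p_bg = p_bg),
            class = "cluster_model")
}

#' Estimate per-region-class background edit-site rates
#'
#' For each region class (5'UTR, CDS, 3'UTR, intron): the number of
#' passing-filter edit sites divided by the number of covered C positions in
#' that class. Classes without coverage inherit the global rate. Typically
#' computed on the buffer-only control, whose editing represents the artifact
#' baseline.
#'
#' @param sites filtered edit sites (possibly pooled across replicates, as a
#'   list or single data.frame)
#' @param counts matching count table(s)
#' @param annotation a `feature_annotation`
#' @return named numeric vector of rates for classes `five_utr`, `cds`,
#'   `three_utr`, `intron`, plus `global`
#' @export
estimate_background_rate <- function(sites, counts, annotation) {
  if (is.data.frame(sites)) sites <- list(sites)
  if (is.data.frame(counts)) counts <- list(counts)
  fx <- gene_features(annotation)
  fx_gr <- .as_granges(fx)
  classes <- c(.exonic_types(), "intron")

  n_sites <- setNames(numeric(length(classes)), classes)
  n_cov <- setNames(numeric(length(classes)), classes)
  tot_sites <- 0
  tot_cov <- 0
  for (i in seq_along(counts)) {
    cov <- counts[[i]][counts[[i]]$ref_count + counts[[i]]$alt_count > 0, ]
    st <- sites[[i]]
    cov_gr <- .pos_granges(cov$chrom, cov$pos0, cov$strand)
    st_gr <- .pos_granges(st$chrom, st$pos0, st$strand)
    cov_f <- GenomicRanges::findOverlaps(cov_gr, fx_gr, ignore.strand = FALSE)
    st_f <- GenomicRanges::findOverlaps(st_gr, fx_gr, ignore.strand = FALSE)
    cov_cls <- fx$type[S4Vectors::subjectHits(cov_f)]
    st_cls <- fx$type[S4Vectors::subjectHits(st_f)]
    for (cl in classes) {
      n_cov[cl] <- n_cov[cl] + sum(cov_cls == cl)
      n_sites[cl] <- n_sites[cl] + sum(st_cls == cl)
    }
    tot_cov <- tot_cov + nrow(cov)
    tot_sites <- tot_sites + nrow(st)
  }
  if (tot_cov == 0) stop("no covered C positions anywhere")
  global <- tot_sites / tot_cov
  rates <- ifelse(n_cov > 0, n_sites / n_cov, global)
  c(setNames(as.numeric(rates), classes), global = global)
}

#' Tile a set of features with sliding windows
#' @noRd
.feature_windows <- function(fx, window_len, window_step) {
  out <- vector("list", nrow(fx))
  for (i in seq_len(nrow(fx))) {
    s <- fx$start0[i]; e <- fx$end0[i]
    if (e - s <= window_len) {
      ws <- s
      we <- e
    } else {
      ws <- seq(s, e - window_len, by = window_step)
      if (ws[length(ws)] < e - window_len) ws <- c(ws, e - window_len)
      we <- ws + window_len
    }
    out[[i]] <- data.frame(
      chrom = fx$chrom[i], start0 = ws, end0 = we, strand = fx$strand[i],
      class = fx$type[i], stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call edit clusters with a Poisson window model and BH-FDR control
#'
#' Windows of `window_len` stepped by `window_step` tile every annotated
#' segment that contains at least one filtered edit site. Per window, the
#' observed count k is the number of edit sites it contains and the expected
#' count is the region-class background rate times the number of covered C
#' positions in the window (floored at 1e-6). Window p-values are Poisson
#' upper tails, adjusted genome-wide by Benjamini-Hochberg; windows with
#' q below `fdr_threshold` are merged per strand when separated by at most
#' `merge_distance` nt, take the minimum member p/q, and are trimmed to the
#' outermost edit sites they contain.
#'
#' @param sites filtered edit sites (one replicate)
#' @param counts the matching count table (supplies covered C positions)
#' @param annotation a `feature_annotation`
#' @param model a [cluster_model()]
#' @return cluster data.frame: chrom, start0, end0, strand, n_edit_sites,
#'   p_value, q_value, score (-log10 q); non-overlapping per strand
#' @export
call_edit_clusters <- function(sites, counts, annotation, model) {
  if (nrow(sites) == 0L) return(.empty_clusters())
  fx <- gene_features(annotation)
  site_gr <- .pos_granges(sites$chrom, sites$pos0, sites$strand)
  keep <- GenomicRanges::countOverlaps(.as_granges(fx), site_gr,
                                       ignore.strand = FALSE) > 0
  fx <- fx[keep, , drop = FALSE]
  if (!nrow(fx)) return(.empty_clusters())

  win <- .feature_windows(fx, model$window_len, model$window_step)
  win_gr <- .as_granges(win)
  cov <- counts[counts$ref_count + counts$alt_count > 0, ]
  cov_gr <- .pos_granges(cov$chrom, cov$pos0, cov$strand)
  k <- GenomicRanges::countOverlaps(win_gr, site_gr, ignore.strand = FALSE)
  n_c <- GenomicRanges::countOverlaps(win_gr, cov_gr, ignore.strand = FALSE)

  rate <- model$p_bg[win$class]
  rate[is.na(rate)] <- model$p_bg[["global"]]
  lam <- pmax(unname(rate) * n_c, 1e-6)
  p <- poisson_tail(k, lam)
  q <- bh_fdr(p)

  sig <- which(q < model$fdr_threshold & k > 0)
  if (!length(sig)) return(.empty_clusters())

  sig_gr <- win_gr[sig]
  merged <- GenomicRanges::reduce(sig_gr, ignore.strand = FALSE,
                                  min.gapwidth = model$merge_distance + 1L,
                                  with.revmap = TRUE)
  revmap <- S4Vectors::mcols(merged)$revmap
  grp <- factor(rep(seq_along(merged), lengths(revmap)),
                levels = seq_along(merged))
  memb <- sig[unlist(revmap)]
  min_p <- vapply(split(p[memb], grp), min, numeric(1))
  min_q <- vapply(split(q[memb], grp), min, numeric(1))

  hits <- GenomicRanges::findOverlaps(merged, site_gr, ignore.strand = FALSE)
  qh <- factor(S4Vectors::queryHits(hits), levels = seq_along(merged))
  sp <- sites$pos0[S4Vectors::subjectHits(hits)]
  first <- vapply(split(sp, qh), min, numeric(1))
  last <- vapply(split(sp, qh), max, numeric(1))
  n_sites <- as.integer(table(factor(qh, levels = seq_along(merged))))

  res <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start0 = as.integer(first), end0 = as.integer(last) + 1L,
    strand = as.character(GenomicRanges::strand(merged)),
    n_edit_sites = n_sites,
    p_value = unname(min_p), q_value = unname(min_q),
    stringsAsFactors = FALSE
  )
  res$score <- -log10(pmax(res$q_value, .Machine$double.xmin))
  res <- res[order(res$chrom, res$start0), ]
  rownames(res) <- NULL
  res
}
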
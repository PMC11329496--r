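## Shared fixtures and independent oracles for the test suite.
## Expensive simulation runs are memoised so several test files can share them.

.memo <- new.env(parent = emptyenv())

memoise_fixture <- function(key, fn) {
  if (!exists(key, envir = .memo)) assign(key, fn(), envir = .memo)
  get(key, envir = .memo)
}

## ---- reference study conditions (short-read pipeline), seed 1 ------------

default_reference <- function() {
  memoise_fixture("default_reference", function() {
    generate_reference(sim_config(seed = 1))
  })
}

default_run <- function() {
  memoise_fixture("default_run", function() {
    suppressMessages(run_pipeline(pipeline_config(sim = sim_config(seed = 1),
                                                  seed = 1)))
  })
}

## ---- long-read study conditions, seed 1 ----------------------------------

longread_run <- function() {
  memoise_fixture("longread_run", function() {
    cfg <- long_read_config(seed = 1)
    ref <- generate_reference(cfg)
    tabs <- list()
    for (cond in c("case", "enzyme_only")) {
      for (r in seq_len(cfg$n_replicates)) {
        tabs[[paste0(cond, "_rep", r)]] <-
          simulate_long_reads(ref, cfg, cond, r)
      }
    }
    filt <- lapply(tabs, filter_long_reads)
    pruned <- remove_putative_snps(filt, ref$truth$snps)
    prof <- editsC_profiles(pruned, ref$annotation)
    case_samples <- paste0("case_rep", seq_len(cfg$n_replicates))
    pf <- filter_isoforms(prof, case_samples = case_samples)
    sel <- select_confident_isoforms(
      pf[pf$sample %in% case_samples, ],
      pf[!pf$sample %in% case_samples, ]
    )
    list(cfg = cfg, ref = ref, raw = tabs, filtered = filt, pruned = pruned,
         profiles = prof, passing = pf, selected = sel,
         case_samples = case_samples,
         bound = bound_transcripts(ref))
  })
}

## Planted bound isoforms: transcripts whose exons contain a truth motif
bound_transcripts <- function(ref) {
  fx <- ref$annotation$features
  tx <- ref$annotation$transcripts
  m <- ref$truth$motifs
  tx$transcript_id[vapply(tx$transcript_id, function(tid) {
    ex <- fx[fx$transcript_id == tid & fx$type %in% c("five_utr", "cds", "three_utr"), ]
    nrow(m) > 0 && any(vapply(seq_len(nrow(m)), function(k) {
      any(m$start0[k] >= ex$start0 & m$end0[k] <= ex$end0)
    }, logical(1)))
  }, logical(1))]
}

## Fraction of truth motifs with a cluster within d nt (recovery)
motif_recovery <- function(clusters, motifs, d = 200L) {
  if (!nrow(clusters)) return(0)
  mg <- GenomicRanges::GRanges(
    motifs$chrom,
    IRanges::IRanges(pmax(motifs$start0 + 1L - d, 1L), motifs$end0 + d),
    motifs$strand
  )
  cg <- GenomicRanges::GRanges(clusters$chrom,
                               IRanges::IRanges(clusters$start0 + 1L,
                                                clusters$end0),
                               clusters$strand)
  mean(GenomicRanges::countOverlaps(mg, cg, ignore.strand = FALSE) > 0)
}

## Fraction of clusters lying within d nt of a truth motif (precision)
cluster_precision <- function(clusters, motifs, d = 200L) {
  if (!nrow(clusters)) return(NA_real_)
  mg <- GenomicRanges::GRanges(
    motifs$chrom,
    IRanges::IRanges(pmax(motifs$start0 + 1L - d, 1L), motifs$end0 + d),
    motifs$strand
  )
  cg <- GenomicRanges::GRanges(clusters$chrom,
                               IRanges::IRanges(clusters$start0 + 1L,
                                                clusters$end0),
                               clusters$strand)
  mean(GenomicRanges::countOverlaps(cg, mg, ignore.strand = FALSE) > 0)
}

## ---- hand-built toy reference for pileup / motif-scan fixtures -----------

## chr1 layout (0-based):
##   [10, 110)  gene "gp" on + : one exon, sequence repeats "ACGT.."
##   [150, 250) gene "gm" on - : one exon
## Sequence is fixed so C / G positions are known by construction.
toy_reference <- function() {
  set.seed(42)
  base <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  ## plant one + motif TGCATG at 40 (inside gp) and the reverse complement
  ## CATGCA at 200 (inside gm, sense UGCAUG on -)
  base[41:46] <- strsplit("TGCATG", "")[[1]]
  base[201:206] <- strsplit("CATGCA", "")[[1]]
  genome <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(genome) <- "chr1"
  genes <- data.frame(
    gene_id = c("gp", "gm"), chrom = "chr1",
    start0 = c(10L, 150L), end0 = c(110L, 250L),
    strand = c("+", "-"), stringsAsFactors = FALSE
  )
  transcripts <- data.frame(
    transcript_id = c("gp.t1", "gm.t1"), gene_id = c("gp", "gm"),
    primary = TRUE, stringsAsFactors = FALSE
  )
  features <- data.frame(
    chrom = "chr1", start0 = c(10L, 150L), end0 = c(110L, 250L),
    strand = c("+", "-"), gene_id = c("gp", "gm"),
    transcript_id = c("gp.t1", "gm.t1"), type = "cds",
    stringsAsFactors = FALSE
  )
  list(genome = genome,
       annotation = feature_annotation(genes, transcripts, features),
       base = base)
}

## Write a minimal SAM file of ungapped single-end reads
write_toy_sam <- function(reads, path, ref_len = 300L) {
  con <- file(path, "w")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:chr1\tLN:%d", ref_len)), con)
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    writeLines(sprintf("%s\t%d\tchr1\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                       r$qname, r$flag, r$pos1, nchar(r$seq), r$seq,
                       strrep("I", nchar(r$seq))), con)
  }
  close(con)
  path
}

## ---- independent oracles --------------------------------------------------

## Poisson upper tail by direct pmf summation
bf_poisson_tail <- function(k, lam, kmax = 1000L) {
  i <- k:max(kmax, k + 60L)
  sum(exp(-lam + i * log(lam) - lgamma(i + 1)))
}

## Textbook BH step-up definition
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

## Exhaustive-window brute force of the cluster caller (loops everywhere)
bf_clusters <- function(sites, counts, annotation, model) {
  fx <- gene_features(annotation)
  cov <- counts[counts$ref_count + counts$alt_count > 0, ]
  win <- list()
  for (i in seq_len(nrow(fx))) {
    in_f <- sites$chrom == fx$chrom[i] & sites$strand == fx$strand[i] &
      sites$pos0 >= fx$start0[i] & sites$pos0 < fx$end0[i]
    if (!any(in_f)) next
    s <- fx$start0[i]; e <- fx$end0[i]
    starts <- if (e - s <= model$window_len) s else {
      st <- seq(s, e - model$window_len, by = model$window_step)
      if (st[length(st)] < e - model$window_len) st <- c(st, e - model$window_len)
      st
    }
    for (ws in starts) {
      we <- min(ws + model$window_len, e)
      if (e - s <= model$window_len) we <- e
      k <- sum(sites$chrom == fx$chrom[i] & sites$strand == fx$strand[i] &
                 sites$pos0 >= ws & sites$pos0 < we)
      nc <- sum(cov$chrom == fx$chrom[i] & cov$strand == fx$strand[i] &
                  cov$pos0 >= ws & cov$pos0 < we)
      rate <- model$p_bg[[fx$type[i]]]
      if (is.null(rate) || is.na(rate)) rate <- model$p_bg[["global"]]
      lam <- max(rate * nc, 1e-6)
      win[[length(win) + 1]] <- data.frame(
        chrom = fx$chrom[i], start0 = ws, end0 = we, strand = fx$strand[i],
        k = k, p = bf_poisson_tail(k, lam), stringsAsFactors = FALSE
      )
    }
  }
  if (!length(win)) return(.empty_clusters_bf())
  w <- do.call(rbind, win)
  w$q <- bf_bh(w$p)
  w <- w[w$q < model$fdr_threshold & w$k > 0, ]
  if (!nrow(w)) return(.empty_clusters_bf())
  out <- list()
  for (strand in unique(w$strand)) {
    ws <- w[w$strand == strand, ]
    ws <- ws[order(ws$start0), ]
    cur <- ws[1, ]
    members <- list(cur)
    flush <- function(members) {
      m <- do.call(rbind, members)
      span_s <- min(m$start0); span_e <- max(m$end0)
      in_cl <- sites$strand == strand & sites$pos0 >= span_s &
        sites$pos0 < span_e
      pos <- sites$pos0[in_cl]
      data.frame(chrom = m$chrom[1], start0 = min(pos),
                 end0 = max(pos) + 1L, strand = strand,
                 n_edit_sites = sum(in_cl), p_value = min(m$p),
                 q_value = min(m$q), stringsAsFactors = FALSE)
    }
    if (nrow(ws) >= 2) {
      for (j in 2:nrow(ws)) {
        gap <- ws$start0[j] - max(vapply(members, function(x) x$end0, numeric(1)))
        if (gap <= model$merge_distance) {
          members[[length(members) + 1]] <- ws[j, ]
        } else {
          out[[length(out) + 1]] <- flush(members)
          members <- list(ws[j, ])
        }
      }
    }
    out[[length(out) + 1]] <- flush(members)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start0), ]
  rownames(res) <- NULL
  res
}

.empty_clusters_bf <- function() {
  data.frame(chrom = character(), start0 = integer(), end0 = integer(),
             strand = character(), n_edit_sites = integer(),
             p_value = numeric(), q_value = numeric(),
             stringsAsFactors = FALSE)
}

## Numerical Beta-posterior tail oracle (quadrature, independent of pbeta)
bf_posterior_tail <- function(alt, ref, p_bg) {
  dens <- function(x) x^(alt - 0.5) * (1 - x)^(ref - 0.5)
  z <- integrate(dens, 0, 1, rel.tol = 1e-12)$value
  integrate(dens, p_bg, 1, rel.tol = 1e-12)$value / z
}

## Minimal long-read table constructor for hand fixtures
mk_reads <- function(n, quality = 30, mapped = TRUE, secondary = FALSE,
                     supplementary = FALSE, strand = "+", tx_strand = "+",
                     isoform = "g001.t1", edited = 0L, total = 10L,
                     positions = "") {
  data.frame(
    read_id = sprintf("r%03d", seq_len(n)), isoform_id = isoform,
    gene_id = sub("\\.t\\d$", "", isoform), mapped = mapped,
    secondary = secondary, supplementary = supplementary,
    quality = quality, strand = strand, tx_strand = tx_strand,
    edited_C = edited, total_C = total, edit_positions = positions,
    stringsAsFactors = FALSE
  )
}

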
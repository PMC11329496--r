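test_that("config validation rejects inconsistent rates and accepts no-editing", {
  expect_error(sim_config(p_bg_buffer = 0.01, p_bg_enzyme = 0.001), "rates")
  expect_error(sim_config(p_bound = 0.001, p_bg_enzyme = 0.002), "rates")
  expect_error(sim_config(snp_fraction = 0.5), "snp_fraction")
  expect_s3_class(sim_config(p_bound = 0, p_bg_enzyme = 0, p_bg_buffer = 0),
                  "sim_config")
})

test_that("minimal reference: one gene, one exon, one planted motif", {
  cfg <- sim_config(n_genes = 1, exons_per_gene = c(1, 1),
                    exon_len = c(300, 300), n_bound_motifs = 1,
                    n_snps = 0, seed = 5)
  ref <- generate_reference(cfg)
  fx <- ref$annotation$features
  expect_equal(nrow(fx), 1L)
  expect_equal(fx$end0 - fx$start0, 300L)
  m <- ref$truth$motifs
  expect_equal(nrow(m), 1L)
  expect_gte(m$start0, fx$start0)
  expect_lte(m$end0, fx$end0)
  ## the sense-strand motif sequence is really in the genome
  seq <- as.character(Biostrings::subseq(ref$genome[[1]],
                                         m$start0 + 1, m$end0))
  expected <- if (m$strand == "+") "TGCATG" else "CATGCA"
  expect_equal(seq, expected)
})

test_that("reference generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 6, seed = 9, intron_len = c(200, 400))
  a <- generate_reference(cfg)
  b <- generate_reference(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$annotation$features, b$annotation$features)
  expect_identical(a$truth, b$truth)
})

test_that("planted motif count is confirmed by an independent string search", {
  ref <- default_reference()
  gseq <- as.character(ref$genome[[1]])
  genes <- ref$annotation$genes
  n_hits <- 0L
  for (i in seq_len(nrow(genes))) {
    sub <- substr(gseq, genes$start0[i] + 1, genes$end0[i])
    pat <- if (genes$strand[i] == "+") "TGCATG" else "CATGCA"
    mm <- gregexpr(paste0("(?=", pat, ")"), sub, perl = TRUE)[[1]]
    n_hits <- n_hits + sum(mm > 0)
  }
  expect_gte(n_hits, nrow(ref$truth$motifs))
  expect_equal(nrow(ref$truth$motifs), 30L)
})

test_that("site counts honour the zero-rate and determinism contracts", {
  cfg <- sim_config(n_genes = 4, p_bound = 0, p_bg_enzyme = 0,
                    p_bg_buffer = 0, n_snps = 0, seed = 3,
                    intron_len = c(200, 400))
  ref <- generate_reference(cfg)
  for (cond in c("case", "enzyme_only", "buffer_only")) {
    tab <- simulate_site_counts(ref, cfg, cond, 1)
    expect_true(all(tab$alt_count == 0))
  }
  cfg2 <- sim_config(n_genes = 4, seed = 3, intron_len = c(200, 400))
  ref2 <- generate_reference(cfg2)
  t1 <- simulate_site_counts(ref2, cfg2, "case", 2)
  t2 <- simulate_site_counts(ref2, cfg2, "case", 2)
  expect_identical(t1, t2)
  t3 <- simulate_site_counts(ref2, cfg2, "case", 3)
  expect_false(identical(t1$alt_count, t3$alt_count))
  expect_error(simulate_site_counts(ref2, cfg2, "mystery", 1))
})

test_that("background edit fractions converge to the configured rates", {
  ref <- default_reference()
  cfg <- ref$config
  tab <- simulate_site_counts(ref, cfg, "buffer_only", 1)
  keep <- !ref$c_sites$is_snp
  n_reads <- sum(tab$ref_count[keep] + tab$alt_count[keep])
  frac <- sum(tab$alt_count[keep]) / n_reads
  se <- sqrt(cfg$p_bg_buffer * (1 - cfg$p_bg_buffer) / n_reads)
  expect_lt(abs(frac - cfg$p_bg_buffer), 3 * se)

  ## case exceeds enzyme-only at bound sites for p_bound > p_bg_enzyme
  bound <- ref$c_sites$dist_motif <= cfg$edit_radius & keep
  case_tab <- simulate_site_counts(ref, cfg, "case", 1)
  enz_tab <- simulate_site_counts(ref, cfg, "enzyme_only", 1)
  f_case <- sum(case_tab$alt_count[bound]) /
    sum(case_tab$ref_count[bound] + case_tab$alt_count[bound])
  f_enz <- sum(enz_tab$alt_count[bound]) /
    sum(enz_tab$ref_count[bound] + enz_tab$alt_count[bound])
  expect_gt(f_case, f_enz)
})

test_that("SNP sites carry the planted apparent fraction in all conditions", {
  ref <- default_reference()
  cfg <- ref$config
  snp <- ref$c_sites$is_snp
  for (cond in c("case", "enzyme_only", "buffer_only")) {
    tab <- simulate_site_counts(ref, cfg, cond, 1)
    covered <- snp & tab$ref_count + tab$alt_count > 0
    frac <- tab$alt_count[covered] /
      (tab$ref_count[covered] + tab$alt_count[covered])
    expect_true(all(frac >= cfg$snp_fraction))
  }
})

test_that("long reads plant filterable defects and follow the edit model", {
  cfg <- long_read_config(seed = 2, n_genes = 20, n_bound_motifs = 2)
  ref <- generate_reference(cfg)
  reads <- simulate_long_reads(ref, cfg, "case", 1)
  expect_true(all(reads$edited_C <= reads$total_C))
  expect_identical(simulate_long_reads(ref, cfg, "case", 1), reads)

  ## edited_C agrees with the edit position list
  n_pos <- vapply(strsplit(reads$edit_positions, ";"),
                  function(x) sum(nzchar(x)), integer(1))
  expect_equal(n_pos, reads$edited_C)

  ## uniform-rate binomial expectation on the enzyme-only arm
  cfg0 <- long_read_config(seed = 2, n_genes = 20, n_bound_motifs = 2,
                           n_snps = 0, contaminant_fraction = 0)
  ref0 <- generate_reference(cfg0)
  r0 <- simulate_long_reads(ref0, cfg0, "enzyme_only", 1)
  tot <- sum(r0$total_C)
  expected <- tot * cfg0$p_bg_enzyme
  se <- sqrt(tot * cfg0$p_bg_enzyme * (1 - cfg0$p_bg_enzyme))
  expect_lt(abs(sum(r0$edited_C) - expected), 3 * se)

  ## zero-rate long reads carry no edits
  cfgz <- sim_config(n_genes = 3, p_bound = 0, p_bg_enzyme = 0,
                     p_bg_buffer = 0, n_snps = 0, seed = 4,
                     intron_len = c(200, 400))
  refz <- generate_reference(cfgz)
  rz <- simulate_long_reads(refz, cfgz, "case", 1)
  expect_true(all(rz$edited_C == 0))
})

test_that("exon skipping produces a clean second isoform", {
  cfg <- long_read_config(seed = 7, n_genes = 30, exons_per_gene = c(3, 4),
                          exon_skipping = TRUE, skip_prob = 1)
  ref <- generate_reference(cfg)
  tx <- ref$annotation$transcripts
  expect_gt(sum(!tx$primary), 0)
  fx <- ref$annotation$features
  for (tid in tx$transcript_id[!tx$primary]) {
    t2 <- fx[fx$transcript_id == tid, ]
    t1 <- fx[fx$transcript_id == sub("t2$", "t1", tid), ]
    ex2 <- t2[t2$type %in% c("five_utr", "cds", "three_utr"), ]
    ex1 <- t1[t1$type %in% c("five_utr", "cds", "three_utr"), ]
    expect_equal(nrow(ex2), nrow(ex1) - 1L)
    expect_true(all(ex2$start0 %in% ex1$start0))
  }
})

test_that("fixture bundles round-trip through the package readers", {
  cfg <- sim_config(n_genes = 8, seed = 6, intron_len = c(200, 500),
                    n_bound_motifs = 4, n_snps = 5)
  ref <- generate_reference(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(ref, dir, long_reads = TRUE)

  ann2 <- read_gtf(file.path(dir, "annotation.gtf"))
  key <- function(f) {
    f <- f[order(f$transcript_id, f$start0, f$type), ]
    rownames(f) <- NULL
    f[, c("chrom", "start0", "end0", "strand", "gene_id", "transcript_id",
          "type")]
  }
  expect_equal(key(ann2$features), key(ref$annotation$features))

  motifs <- read_bed(file.path(dir, "truth_motifs.bed"))
  expect_equal(nrow(motifs), cfg$n_bound_motifs)
  expect_equal(motifs$start0, ref$truth$motifs$start0)

  genome2 <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_gte(Biostrings::width(genome2)[1], max(ann2$genes$end0))
  expect_equal(Biostrings::width(genome2), Biostrings::width(ref$genome))

  counts2 <- read_site_counts(file.path(dir, "sites_case_rep1.tsv"))
  expect_equal(counts2, simulate_site_counts(ref, cfg, "case", 1))

  reads2 <- read_long_reads(file.path(dir, "reads_case_rep1.tsv"))
  reads1 <- simulate_long_reads(ref, cfg, "case", 1)
  expect_equal(reads2$edited_C, reads1$edited_C)
  expect_equal(reads2$edit_positions, reads1$edit_positions)
})
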
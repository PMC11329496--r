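test_that("motif scan reports sense-strand occurrences inside genes", {
  toy <- toy_reference()
  hits <- scan_motif(toy$genome, toy$annotation, "UGCAUG")
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  expect_true(any(plus$start0 == 40 & plus$end0 == 46))
  expect_true(any(minus$start0 == 200 & minus$end0 == 206))
  expect_true(all(hits$end0 - hits$start0 == 6))
  expect_error(scan_motif(toy$genome, toy$annotation, "UGCAXG"), "motif")
})

test_that("motif scan agrees with an independent regex scan of gene sequences", {
  ref <- default_reference()
  hits <- scan_motif(ref$genome, ref$annotation, ref$config$motif)
  n_regex <- 0L
  for (i in seq_len(nrow(ref$annotation$genes))) {
    g <- ref$annotation$genes[i, ]
    seq <- Biostrings::subseq(ref$genome[[g$chrom]], g$start0 + 1, g$end0)
    if (g$strand == "-") seq <- Biostrings::reverseComplement(seq)
    ## lookahead so overlapping occurrences are counted too
    mm <- gregexpr("(?=TGCATG)", as.character(seq), perl = TRUE)[[1]]
    n_regex <- n_regex + sum(mm > 0)
  }
  expect_equal(nrow(hits), n_regex)
})

test_that("motif fraction is an overlap ratio with exact edge behaviour", {
  cl <- data.frame(chrom = "chr1", start0 = c(0L, 100L, 200L),
                   end0 = c(50L, 150L, 250L), strand = "+",
                   stringsAsFactors = FALSE)
  hits <- data.frame(chrom = "chr1", start0 = c(49L, 150L),
                     end0 = c(55L, 156L), strand = "+",
                     stringsAsFactors = FALSE)
  ## 1-nt overlap counts; half-open adjacency does not
  expect_equal(motif_fraction(cl, hits), 1 / 3)
  expect_equal(motif_fraction(cl, cl), 1)
  expect_equal(motif_fraction(cl, hits[0, ]), 0)
  expect_error(motif_fraction(cl[0, ], hits), "empty")
  ## opposite strand does not count
  hits$strand <- "-"
  expect_equal(motif_fraction(cl, hits), 0)
})

test_that("peak overlap fraction handles identity and disjoint cases", {
  cl <- data.frame(chrom = "chr1", start0 = c(0L, 100L), end0 = c(50L, 150L),
                   strand = "+", stringsAsFactors = FALSE)
  expect_equal(overlap_fraction(cl, cl), 1)
  peaks <- data.frame(chrom = "chr2", start0 = 0L, end0 = 1000L,
                      strand = "+", stringsAsFactors = FALSE)
  expect_equal(overlap_fraction(cl, peaks), 0)
  expect_error(overlap_fraction(cl[0, ], peaks), "empty")
})

test_that("shuffles preserve length, strand and host feature", {
  run <- default_run()
  ann <- run$annotation
  cl <- run$confident$case
  fx <- gene_features(ann)
  perms <- shuffle_clusters(cl, ann, n_perm = 5, seed = 3)
  mid0 <- floor((cl$start0 + cl$end0 - 1) / 2)
  host_of <- function(mid, strand) {
    which(fx$start0 <= mid & fx$end0 > mid & fx$strand == strand)[1]
  }
  host <- mapply(host_of, mid0, cl$strand)
  for (p in perms) {
    expect_equal(p$end0 - p$start0,
                 pmin(cl$end0 - cl$start0, fx$end0[host] - fx$start0[host]))
    expect_equal(p$strand, cl$strand)
    expect_true(all(p$start0 >= fx$start0[host] & p$end0 <= fx$end0[host]))
  }
  ## same seed reproduces, different seed varies
  perms2 <- shuffle_clusters(cl, ann, n_perm = 5, seed = 3)
  expect_identical(perms, perms2)
  perms3 <- shuffle_clusters(cl, ann, n_perm = 5, seed = 4)
  expect_false(identical(perms, perms3))
})

test_that("a cluster spanning its whole host feature is clamped in place", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", start0 = 0L,
                      end0 = 100L, strand = "+", stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = "g.t1", gene_id = "g", primary = TRUE,
                   stringsAsFactors = FALSE)
  fx <- data.frame(chrom = "chr1", start0 = 0L, end0 = 100L, strand = "+",
                   gene_id = "g", transcript_id = "g.t1", type = "cds",
                   stringsAsFactors = FALSE)
  ann <- feature_annotation(genes, tx, fx)
  cl <- data.frame(chrom = "chr1", start0 = 0L, end0 = 100L, strand = "+",
                   stringsAsFactors = FALSE)
  perms <- shuffle_clusters(cl, ann, n_perm = 20, seed = 1)
  for (p in perms) expect_equal(p, cl)

  outside <- data.frame(chrom = "chr1", start0 = 500L, end0 = 520L,
                        strand = "+", stringsAsFactors = FALSE)
  expect_error(shuffle_clusters(outside, ann), "outside any feature")
})

test_that("shuffled starts are uniform across the valid offsets", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", start0 = 0L,
                      end0 = 120L, strand = "+", stringsAsFactors = FALSE)
  tx <- data.frame(transcript_id = "g.t1", gene_id = "g", primary = TRUE,
                   stringsAsFactors = FALSE)
  fx <- data.frame(chrom = "chr1", start0 = 0L, end0 = 120L, strand = "+",
                   gene_id = "g", transcript_id = "g.t1", type = "cds",
                   stringsAsFactors = FALSE)
  ann <- feature_annotation(genes, tx, fx)
  cl <- data.frame(chrom = "chr1", start0 = 50L, end0 = 70L, strand = "+",
                   stringsAsFactors = FALSE)
  perms <- shuffle_clusters(cl, ann, n_perm = 10000, seed = 2)
  starts <- vapply(perms, function(p) p$start0, integer(1))
  ## valid starts are 0..100: chi-square goodness of fit against uniform
  expect_true(all(starts >= 0 & starts <= 100))
  tab <- tabulate(starts + 1L, nbins = 101L)
  chisq <- sum((tab - mean(tab))^2 / mean(tab))
  expect_gt(pchisq(chisq, df = 100, lower.tail = FALSE), 0.001)
})

test_that("permutation summaries compute z and enrichment as defined", {
  s <- permutation_enrichment(0.2, c(0.1, 0.2, 0.3))
  expect_equal(s$z_score, 0)
  expect_equal(s$enrichment, 1)

  expect_message(
    s2 <- permutation_enrichment(0.10, rep(0.025, 20)),
    "z undefined"
  )
  expect_equal(s2$enrichment, 4)
  expect_true(is.na(s2$z_score))

  withr::with_seed(12, {
    perm <- runif(20, 0.01, 0.06)
    s3 <- permutation_enrichment(0.4, perm)
    expect_equal(s3$z_score, (0.4 - mean(perm)) / sd(perm))
    expect_equal(s3$enrichment, 0.4 / mean(perm))
  })

  expect_message(s4 <- permutation_enrichment(0.3, c(0, 0)), "infinite")
  expect_true(is.infinite(s4$enrichment))
  expect_error(permutation_enrichment(0.1, 0.2), "2 permuted")
})

test_that("nearest distances are signed, strand-oriented and tie-broken", {
  cl <- data.frame(chrom = "chr1", start0 = c(100L, 100L), end0 = c(110L, 110L),
                   strand = c("+", "-"), stringsAsFactors = FALSE)
  tg <- data.frame(chrom = "chr1", start0 = 200L, end0 = 210L, strand = "+",
                   stringsAsFactors = FALSE)
  d <- nearest_feature_distance(cl, tg)
  expect_equal(d, c(100, -100))  # sign flips on the minus strand

  ## concentric -> 0
  expect_equal(nearest_feature_distance(cl[1, ], cl[1, ]), 0)

  ## equidistant targets: tie goes to the upstream (negative) side
  tg2 <- data.frame(chrom = "chr1", start0 = c(54L, 154L),
                    end0 = c(56L, 156L), strand = "+",
                    stringsAsFactors = FALSE)
  d2 <- nearest_feature_distance(cl[1, ], tg2)
  expect_equal(d2, -50)
})

test_that("nearest distances match an exhaustive pairwise scan", {
  withr::with_seed(31, {
    cl <- data.frame(chrom = "chr1", start0 = sort(sample(0:5000, 5)),
                     strand = sample(c("+", "-"), 5, replace = TRUE),
                     stringsAsFactors = FALSE)
    cl$end0 <- cl$start0 + sample(10:60, 5)
    tg <- data.frame(chrom = "chr1", start0 = sort(sample(0:5000, 7)),
                     strand = "+", stringsAsFactors = FALSE)
    tg$end0 <- tg$start0 + 6L
    got <- nearest_feature_distance(cl, tg)
    cm <- floor((cl$start0 + cl$end0 - 1) / 2)
    tm <- floor((tg$start0 + tg$end0 - 1) / 2)
    for (i in 1:5) {
      d <- tm - cm[i]
      if (cl$strand[i] == "-") d <- -d
      best <- d[abs(d) == min(abs(d))]
      expect_equal(got[i], min(best))
    }
  })
})

test_that("edit radius locates where the case excess stops accumulating", {
  expect_equal(edit_radius(c(1, 5, 10), c(1, 5, 10)), 0)
  withr::with_seed(41, {
    case_d <- runif(2000, 0, 50)
    ctrl_d <- runif(5000, 0, 1000)
    r <- edit_radius(case_d, ctrl_d)
    expect_lte(r, 60)
    expect_gte(r, 30)
  })
})

test_that("the simulated 200 nt editing radius is recovered", {
  run <- default_run()
  expect_gte(run$radius, 150)
  expect_lte(run$radius, 250)
  ## distances measured against the planted truth motifs agree
  truth <- default_reference()$truth$motifs
  site_iv <- function(s) data.frame(chrom = s$chrom, start0 = s$pos0,
                                    end0 = s$pos0 + 1L, strand = s$strand,
                                    stringsAsFactors = FALSE)
  d_case <- nearest_feature_distance(site_iv(run$sites$case[[1]]), truth)
  d_enz <- nearest_feature_distance(site_iv(run$sites$enzyme_only[[1]]), truth)
  r_truth <- edit_radius(d_case, d_enz)
  expect_gte(r_truth, 150)
  expect_lte(r_truth, 250)
})
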
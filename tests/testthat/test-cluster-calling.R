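test_that("poisson tail matches direct pmf summation and handles edges", {
  expect_equal(poisson_tail(0, 5), 1)
  expect_equal(poisson_tail(1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(poisson_tail(10, 1), bf_poisson_tail(10, 1), tolerance = 1e-12)
  expect_error(poisson_tail(1, 0), "lam")
  expect_error(poisson_tail(-1, 1), "k")
  expect_error(poisson_tail(1.5, 1), "k")
})

test_that("BH adjustment matches the textbook step-up definition", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(1, {
    for (i in 1:25) {
      p <- runif(sample(1:200, 1))
      expect_equal(bh_fdr(p), bf_bh(p), tolerance = 1e-12)
    }
    p <- runif(50)
    perm <- sample(50)
    expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

## toy annotation: one + intron-free gene per "class" for rate fixtures
toy_class_annotation <- function() {
  genes <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                      start0 = c(0L, 20000L), end0 = c(10000L, 30000L),
                      strand = "+", stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = c("a.t1", "b.t1"),
                            gene_id = c("a", "b"), primary = TRUE,
                            stringsAsFactors = FALSE)
  features <- data.frame(
    chrom = "chr1", start0 = c(0L, 20000L), end0 = c(10000L, 30000L),
    strand = "+", gene_id = c("a", "b"),
    transcript_id = c("a.t1", "b.t1"), type = c("intron", "cds"),
    stringsAsFactors = FALSE
  )
  feature_annotation(genes, transcripts, features)
}

test_that("background rates are per-class ratios with a global fallback", {
  ann <- toy_class_annotation()
  counts <- data.frame(chrom = "chr1", pos0 = 0:9999, strand = "+",
                       ref_count = 10L, alt_count = 0L,
                       stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos0 = seq(0, 9000, by = 1000),
                      strand = "+", ref_count = 9L, alt_count = 1L,
                      stringsAsFactors = FALSE)
  rates <- estimate_background_rate(sites, counts, ann)
  expect_equal(unname(rates["intron"]), 10 / 10000)
  ## cds has no coverage: inherits the global rate
  expect_equal(unname(rates["cds"]), unname(rates["global"]))
  expect_equal(unname(rates["global"]), 10 / 10000)

  ## removing sites never increases the numerator
  rates2 <- estimate_background_rate(sites[1:5, ], counts, ann)
  expect_lte(rates2[["intron"]], rates[["intron"]])
  expect_error(estimate_background_rate(sites, counts[0, ], ann), "covered")
})

test_that("a dense clump of edit sites becomes a single trimmed cluster", {
  ann <- toy_class_annotation()
  covered <- data.frame(chrom = "chr1", pos0 = 0:9999, strand = "+",
                        ref_count = 49L, alt_count = 0L,
                        stringsAsFactors = FALSE)
  clump <- c(5000L, 5007L, 5013L, 5021L, 5029L)   # 5 sites within 30 nt
  covered$alt_count[covered$pos0 %in% clump] <- 5L
  sites <- call_edit_sites(covered, 0.001)
  sites <- filter_edit_sites(sites)
  model <- cluster_model(p_bg = c(intron = 0.001, cds = 0.001,
                                  five_utr = 0.001, three_utr = 0.001,
                                  global = 0.001))
  cl <- call_edit_clusters(sites, covered, ann, model)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_edit_sites, 5L)
  expect_equal(cl$start0, 5000L)
  expect_equal(cl$end0, 5030L)
  ## manual Poisson + BH on the strongest window: k = 5, lam = 50 * 0.001
  p_manual <- bf_poisson_tail(5, 0.05)
  expect_lte(cl$p_value, p_manual * 1.0001)
  expect_lt(cl$q_value, model$fdr_threshold)
})

test_that("significant windows merge at gaps <= 15 nt and split beyond", {
  ann <- toy_class_annotation()
  covered <- data.frame(chrom = "chr1", pos0 = 0:9999, strand = "+",
                        ref_count = 49L, alt_count = 0L,
                        stringsAsFactors = FALSE)
  mk <- function(clump_b_start) {
    cov <- covered
    clump_a <- 5000:5004
    clump_b <- clump_b_start:(clump_b_start + 4L)
    cov$alt_count[cov$pos0 %in% c(clump_a, clump_b)] <- 5L
    sites <- filter_edit_sites(call_edit_sites(cov, 0.001))
    model <- cluster_model(window_len = 10L, window_step = 10L,
                           p_bg = c(intron = 1e-4, cds = 1e-4,
                                    five_utr = 1e-4, three_utr = 1e-4,
                                    global = 1e-4))
    call_edit_clusters(sites, cov, ann, model)
  }
  ## windows [5000,5010) and [5020,5030): gap 10 <= 15 -> one cluster
  merged <- mk(5020L)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_edit_sites, 10L)
  ## windows [5000,5010) and [5030,5040): gap 20 > 15 -> two clusters
  split <- mk(5030L)
  expect_equal(nrow(split), 2L)
})

test_that("cluster calls match an exhaustive-window brute force", {
  ann <- toy_class_annotation()
  withr::with_seed(21, {
    for (rep in 1:3) {
      covered <- data.frame(chrom = "chr1",
                            pos0 = sort(sample(0:9999, 3000)),
                            strand = "+", ref_count = 30L, alt_count = 0L,
                            stringsAsFactors = FALSE)
      n_edit <- 150
      idx <- sample(nrow(covered), n_edit)
      covered$alt_count[idx] <- sample(1:6, n_edit, replace = TRUE)
      ## add one dense clump so something is significant
      clump <- which(covered$pos0 >= 4000 & covered$pos0 < 4040)
      covered$alt_count[clump] <- 4L
      sites <- filter_edit_sites(call_edit_sites(covered, 0.005))
      model <- cluster_model(p_bg = c(intron = 0.02, cds = 0.02,
                                      five_utr = 0.02, three_utr = 0.02,
                                      global = 0.02))
      got <- call_edit_clusters(sites, covered, ann, model)
      want <- bf_clusters(sites, covered, ann, model)
      expect_equal(got[, c("chrom", "start0", "end0", "strand",
                           "n_edit_sites")],
                   want[, c("chrom", "start0", "end0", "strand",
                            "n_edit_sites")])
      expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
      expect_equal(got$q_value, want$q_value, tolerance = 1e-10)
    }
  })
})

test_that("empty site sets yield empty cluster sets, not errors", {
  ann <- toy_class_annotation()
  covered <- data.frame(chrom = "chr1", pos0 = 0:99, strand = "+",
                        ref_count = 10L, alt_count = 0L,
                        stringsAsFactors = FALSE)
  model <- cluster_model(p_bg = c(global = 0.001))
  cl <- call_edit_clusters(covered[0, ], covered, ann, model)
  expect_equal(nrow(cl), 0L)
})

test_that("cluster model validates its parameters", {
  expect_error(cluster_model(window_len = 10, window_step = 20, p_bg = 1),
               "window_step")
  expect_error(cluster_model(fdr_threshold = 0, p_bg = 1))
})
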
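#' Simulation configuration
#'
#' Defines the generative conditions for a synthetic antibody-directed
#' deaminase editing experiment: a toy stranded transcriptome with planted
#' RBP binding motifs, distance-dependent elevated editing near bound motifs,
#' uniform background editing, enzyme-only and buffer-only control conditions,
#' replicate structure and planted SNP confounders.
#'
#' Defaults describe the reference study conditions used throughout the
#' package's tests: ~100 genes, 30 bound motif instances, a per-read edit
#' probability of 0.05 at bound C sites within 200 nt of a motif, background
#' rates of 0.002 (enzyme present) and 0.0005 (buffer only), 50x coverage and
#' three replicates.
#'
#' @param n_genes number of genes
#' @param exons_per_gene integer range `c(min, max)` of exons per gene
#' @param exon_len,intron_len length ranges in nt
#' @param n_bound_motifs number of bound motif instances planted in
#'   transcribed regions
#' @param motif RNA k-mer bound by the profiled RBP (default `"UGCAUG"`)
#' @param motif_placement `"transcribed"` places motifs length-weighted across
#'   exons and introns; `"exonic"` restricts them to exonic segments
#' @param edit_radius maximal distance (nt) from a bound motif at which
#'   editing is elevated
#' @param p_bound per-read edit probability at bound C sites (case condition,
#'   within `edit_radius` of a motif)
#' @param p_bg_enzyme background per-read edit probability when the enzyme is
#'   present but unbound (case background and enzyme-only condition)
#' @param p_bg_buffer artifact per-read edit probability without enzyme
#'   (buffer-only condition)
#' @param coverage_mean mean reads per site (Poisson)
#' @param n_replicates replicates per condition
#' @param n_snps number of planted SNP confounders
#' @param snp_fraction apparent edit fraction at SNP positions (condition
#'   invariant; must be >= 0.8 so the edit-fraction filter removes them)
#' @param seed master integer seed
#' @param intergenic_gap nt between genes
#' @param exon_skipping if `TRUE`, some genes get a second isoform skipping
#'   one internal exon (long-read simulation)
#' @param skip_prob per-gene probability of carrying a skipping isoform
#' @param reads_per_isoform mean long reads per isoform per replicate
#' @param contaminant_fraction fraction of long reads planted with each
#'   disqualifying property (low quality, unmapped, secondary, supplementary,
#'   wrong strand)
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(n_genes = 100L,
                       exons_per_gene = c(3L, 5L),
                       exon_len = c(150L, 400L),
                       intron_len = c(2000L, 4000L),
                       n_bound_motifs = 30L,
                       motif = "UGCAUG",
                       motif_placement = c("transcribed", "exonic"),
                       edit_radius = 200L,
                       p_bound = 0.05,
                       p_bg_enzyme = 0.002,
                       p_bg_buffer = 5e-4,
                       coverage_mean = 50,
                       n_replicates = 3L,
                       n_snps = 50L,
                       snp_fraction = 0.9,
                       seed = 1L,
                       intergenic_gap = 500L,
                       exon_skipping = FALSE,
                       skip_prob = 0.3,
                       reads_per_isoform = 30,
                       contaminant_fraction = 0.02) {
  motif_placement <- match.arg(motif_placement)
  cfg <- list(
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_len = as.integer(exon_len),
    intron_len = as.integer(intron_len),
    n_bound_motifs = as.integer(n_bound_motifs),
    motif = toupper(motif),
    motif_placement = motif_placement,
    edit_radius = as.integer(edit_radius),
    p_bound = p_bound,
    p_bg_enzyme = p_bg_enzyme,
    p_bg_buffer = p_bg_buffer,
    coverage_mean = coverage_mean,
    n_replicates = as.integer(n_replicates),
    n_snps = as.integer(n_snps),
    snp_fraction = snp_fraction,
    seed = as.integer(seed),
    intergenic_gap = as.integer(intergenic_gap),
    exon_skipping = isTRUE(exon_skipping),
    skip_prob = skip_prob,
    reads_per_isoform = reads_per_isoform,
    contaminant_fraction = contaminant_fraction
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_genes >= 1L,
    length(cfg$exons_per_gene) == 2L, all(cfg$exons_per_gene >= 1L),
    cfg$exons_per_gene[1] <= cfg$exons_per_gene[2],
    all(cfg$exon_len > 0L), all(cfg$intron_len > 0L),
    cfg$exon_len[1] <= cfg$exon_len[2],
    cfg$intron_len[1] <= cfg$intron_len[2],
    cfg$n_bound_motifs >= 0L,
    cfg$edit_radius >= 0L,
    cfg$n_replicates >= 1L,
    cfg$n_snps >= 0L,
    cfg$intergenic_gap >= 0L
  )
  if (!grepl("^[ACGU]+$", cfg$motif)) {
    stop("motif must be an RNA string over {A,C,G,U}: ", cfg$motif)
  }
  rates_ok <- cfg$p_bg_buffer >= 0 && cfg$p_bg_buffer <= cfg$p_bg_enzyme &&
    cfg$p_bound <= 1 &&
    (cfg$p_bg_enzyme < cfg$p_bound || cfg$p_bound == 0)  # all-zero = no editing
  if (!rates_ok) {
    stop("rates must satisfy 0 <= p_bg_buffer <= p_bg_enzyme < p_bound <= 1")
  }
  if (cfg$snp_fraction < 0.8 || cfg$snp_fraction > 1) {
    stop("snp_fraction must lie in [0.8, 1] so the fraction filter removes SNPs")
  }
  invisible(cfg)
}

#' Long-read study conditions
#'
#' Scenario configuration for the isoform-resolved long-read analysis: fewer,
#' exonically bound motifs among many null genes, stronger editing on the
#' scale observed in long-read deaminase profiling (background editsC of
#' order a few percent, several-fold elevation on bound isoforms), two
#' replicates, and alternative isoforms via exon skipping.
#'
#' @param seed master integer seed
#' @param ... overrides passed to [sim_config()]
#' @return a `sim_config`
#' @export
long_read_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_genes = 150L,
    exons_per_gene = c(2L, 3L),
    exon_len = c(100L, 250L),
    intron_len = c(300L, 800L),
    n_bound_motifs = 15L,
    motif_placement = "exonic",
    p_bound = 0.25,
    p_bg_enzyme = 0.03,
    p_bg_buffer = 0.005,
    n_replicates = 3L,
    n_snps = 30L,
    exon_skipping = FALSE,
    reads_per_isoform = 40,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
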
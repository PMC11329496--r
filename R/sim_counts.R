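#' Per-site true edit probability under a condition
#'
#' Step model: within `edit_radius` of a bound motif the case condition edits
#' at `p_bound`; everywhere else (and in enzyme-only) at `p_bg_enzyme`;
#' buffer-only edits at the artifact rate `p_bg_buffer`. SNP positions are
#' handled separately by the samplers (condition-invariant apparent fraction).
#'
#' @noRd
.site_edit_prob <- function(reference, condition) {
  cfg <- reference$config
  cs <- reference$c_sites
  p <- switch(condition,
    case = ifelse(cs$dist_motif <= cfg$edit_radius, cfg$p_bound, cfg$p_bg_enzyme),
    enzyme_only = rep(cfg$p_bg_enzyme, nrow(cs)),
    buffer_only = rep(cfg$p_bg_buffer, nrow(cs)),
    stop("unknown condition: ", condition)
  )
  p
}

#' Simulate a per-site count table for one condition and replicate
#'
#' For every transcribed sense-C position, coverage is Poisson with mean
#' `coverage_mean` and the edited count is Binomial(coverage, p_site). SNP
#' positions get a deterministic apparent edit fraction of at least
#' `snp_fraction` in every condition and replicate (alt = ceiling(coverage *
#' snp_fraction)), so the edit-fraction filter can remove them exactly. The
#' per-table seed is derived from (seed, condition, replicate), so any table
#' is reproducible in isolation.
#'
#' @param reference a `sim_reference` from [generate_reference()]
#' @param config a [sim_config()] (normally `reference$config`)
#' @param condition `"case"`, `"enzyme_only"` or `"buffer_only"`
#' @param replicate 1-based replicate index
#' @return data.frame with columns chrom, pos0, strand, ref_count, alt_count
#' @export
simulate_site_counts <- function(reference, config = reference$config,
                                 condition, replicate) {
  condition <- match.arg(condition, .conditions())
  if (replicate < 1L || replicate > config$n_replicates) {
    stop("replicate index out of range: ", replicate)
  }
  p <- .site_edit_prob(reference, condition)
  cs <- reference$c_sites
  tab_seed <- derive_seed(config$seed, condition, replicate)
  withr::with_seed(tab_seed, {
    coverage <- rpois(nrow(cs), config$coverage_mean)
    alt <- rbinom(nrow(cs), coverage, p)
    if (any(cs$is_snp)) {
      snp <- cs$is_snp
      alt[snp] <- as.integer(ceiling(coverage[snp] * config$snp_fraction))
    }
    data.frame(
      chrom = cs$chrom, pos0 = cs$pos0, strand = cs$strand,
      ref_count = coverage - alt, alt_count = alt,
      stringsAsFactors = FALSE
    )
  })
}
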
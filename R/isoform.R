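#' Filter long reads on mapping, flags, quality and strand
#'
#' Retains reads that are mapped, primary (not secondary), non-supplementary,
#' have mean base quality >= 20 and are aligned to the isoform's annotated
#' strand (`tx_strand` column).
#'
#' @param reads long-read data.frame (schema of [simulate_long_reads()])
#' @param min_quality quality floor, inclusive (default 20)
#' @return filtered read data.frame
#' @export
filter_long_reads <- function(reads, min_quality = 20) {
  keep <- reads$mapped &
    !reads$secondary &
    !reads$supplementary &
    reads$quality >= min_quality &
    reads$strand == reads$tx_strand
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse ";"-joined edit positions into integer vectors
#' @noRd
.edit_pos_list <- function(reads) {
  lapply(strsplit(ifelse(is.na(reads$edit_positions), "",
                         reads$edit_positions), ";", fixed = TRUE),
         function(x) as.integer(x[nzchar(x)]))
}

#' Remove putative SNP positions from long-read edit calls
#'
#' A position is a putative SNP when it carries at least one edited read in
#' every replicate of every sample (true SNPs appear everywhere, targeted
#' editing does not); those positions, plus any position in the known-SNP
#' list, are removed from all edit calls, and per-read edited_C counts are
#' recomputed.
#'
#' @param read_tables named list (>= 2 tables) of long-read data.frames, one
#'   per sample x replicate
#' @param known_snps interval data.frame of annotated SNPs, or `NULL`
#' @return list of read data.frames with pruned edit calls
#' @export
remove_putative_snps <- function(read_tables, known_snps = NULL) {
  if (length(read_tables) < 2L) {
    stop("putative-SNP removal needs >= 2 samples")
  }
  pos_sets <- lapply(read_tables, function(tab) {
    unique(unlist(.edit_pos_list(tab)))
  })
  putative <- Reduce(intersect, pos_sets)
  drop <- putative
  if (!is.null(known_snps) && nrow(known_snps)) {
    drop <- union(drop, known_snps$start0)
  }
  lapply(read_tables, function(tab) {
    ep <- .edit_pos_list(tab)
    ep <- lapply(ep, function(x) setdiff(x, drop))
    tab$edit_positions <- vapply(ep, paste, character(1), collapse = ";")
    tab$edited_C <- vapply(ep, length, integer(1))
    tab
  })
}

#' Per-isoform editsC profile
#'
#' editsC is the ratio of edited C calls to total C calls across the exons
#' and UTRs of an isoform, aggregated over its (filtered) reads:
#' `sum(edited_C) / sum(total_C)`. A zero denominator yields `NA` editsC.
#'
#' @param isoform_id isoform identifier (must exist in the annotation)
#' @param reads filtered read data.frame (all samples/replicates mixed is
#'   allowed; rows are subset by `isoform_id`)
#' @param annotation a `feature_annotation` (validates the isoform)
#' @return one-row data.frame: isoform_id, read_count, total_C_calls,
#'   edited_C_calls, editsC, mean_edit_fraction
#' @export
compute_editsC <- function(isoform_id, reads, annotation = NULL) {
  if (!is.null(annotation) &&
      !isoform_id %in% annotation$transcripts$transcript_id) {
    stop("unknown isoform: ", isoform_id)
  }
  r <- reads[reads$isoform_id == isoform_id, , drop = FALSE]
  tot <- sum(r$total_C)
  ed <- sum(r$edited_C)
  data.frame(
    isoform_id = isoform_id,
    read_count = nrow(r),
    total_C_calls = tot,
    edited_C_calls = ed,
    editsC = if (tot > 0) ed / tot else NA_real_,
    mean_edit_fraction = if (nrow(r) > 0) {
      mean(ifelse(r$total_C > 0, r$edited_C / r$total_C, NA_real_),
           na.rm = TRUE)
    } else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' editsC profiles for every isoform in every sample table
#'
#' @param read_tables named list of filtered read data.frames; names encode
#'   sample/replicate (e.g. `"case_rep1"`)
#' @param annotation a `feature_annotation`
#' @return long-format data.frame with one row per isoform x table: sample
#'   (table name), isoform_id, read_count, total_C_calls, edited_C_calls,
#'   editsC, mean_edit_fraction
#' @export
editsC_profiles <- function(read_tables, annotation) {
  iso <- annotation$transcripts$transcript_id
  out <- list()
  for (nm in names(read_tables)) {
    tab <- read_tables[[nm]]
    prof <- do.call(rbind, lapply(iso, compute_editsC, reads = tab,
                                  annotation = annotation))
    prof$sample <- nm
    out[[nm]] <- prof
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter isoform profiles on coverage and case editing level
#'
#' Retains isoforms with read coverage of at least `min_coverage` in every
#' table and a mean editsC across case tables of at least
#' `min_edit_fraction`. "Coverage across replicates" is interpreted as the
#' minimum over tables (switchable to the mean).
#'
#' @param profiles long-format profiles from [editsC_profiles()]
#' @param case_samples character vector naming the case tables
#' @param min_coverage read-coverage floor, inclusive (default 20)
#' @param min_edit_fraction case-mean editsC floor, inclusive (default 0.02)
#' @param coverage_rule `"min"` (default) or `"mean"` across tables
#' @return profiles restricted to passing isoforms
#' @export
filter_isoforms <- function(profiles, case_samples,
                            min_coverage = 20, min_edit_fraction = 0.02,
                            coverage_rule = c("min", "mean")) {
  coverage_rule <- match.arg(coverage_rule)
  agg_fun <- if (coverage_rule == "min") min else mean
  by_iso <- split(profiles, profiles$isoform_id)
  pass <- vapply(by_iso, function(p) {
    cov_ok <- agg_fun(p$read_count) >= min_coverage
    case_e <- p$editsC[p$sample %in% case_samples]
    edit_ok <- length(case_e) > 0 && !anyNA(case_e) &&
      mean(case_e) >= min_edit_fraction
    cov_ok && edit_ok
  }, logical(1))
  keep_iso <- names(by_iso)[pass]
  out <- profiles[profiles$isoform_id %in% keep_iso, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select case-elevated isoforms from a case-vs-control linear model
#'
#' Fits ordinary least squares of case mean editsC on control mean editsC
#' (with intercept) across isoforms and selects isoforms whose residual
#' exceeds `k_std` sample standard deviations of the residuals (one-sided:
#' only case-elevated isoforms are reported).
#'
#' @param case_profiles,control_profiles long-format profiles (already
#'   filtered) for the case and control tables
#' @param k_std residual threshold in standard deviations (default 1.5)
#' @return character vector of selected isoform ids
#' @export
select_confident_isoforms <- function(case_profiles, control_profiles,
                                      k_std = 1.5) {
  mean_by_iso <- function(p) {
    vapply(split(p$editsC, p$isoform_id), mean, numeric(1), na.rm = TRUE)
  }
  case_m <- mean_by_iso(case_profiles)
  ctrl_m <- mean_by_iso(control_profiles)
  iso <- intersect(names(case_m), names(ctrl_m))
  if (length(iso) < 3L) {
    stop("need >= 3 matched isoforms to fit the case-control model")
  }
  df <- data.frame(case = case_m[iso], ctrl = ctrl_m[iso])
  fit <- lm(case ~ ctrl, data = df)
  r <- residuals(fit)
  sel <- r > k_std * sd(r)
  iso[sel]
}
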
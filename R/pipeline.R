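#' Pipeline configuration
#'
#' Bundles the simulation (or input directory), output directory and every
#' analysis threshold. Threshold defaults mirror the standard printed
#' parameters of the workflow: confidence score > 0.5, edit fraction < 0.8,
#' cluster FDR 0.1, merge distance 15 nt, 20 permutations.
#'
#' @param sim a [sim_config()] describing the dataset to simulate, or `NULL`
#'   when `input_dir` points at an existing fixture bundle
#' @param input_dir directory written by [write_fixture_bundle()], or `NULL`
#' @param out_dir output directory (created); `NULL` keeps results in memory
#' @param score_min,fraction_max edit-site filter thresholds (exclusive)
#' @param p_bg_score fallback scoring background when no buffer-only control
#'   exists (default 0.005)
#' @param window_len,window_step,fdr_threshold,merge_distance cluster model
#' @param motif RNA motif for the enrichment stage
#' @param n_perm permutations for the shuffle test
#' @param grid_max,epsilon edit-radius estimation parameters
#' @param anchor_replicate 1-based index of the replicate anchoring the
#'   intersection
#' @param seed seed for the shuffle stage
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            out_dir = NULL,
                            score_min = 0.5, fraction_max = 0.8,
                            p_bg_score = 0.005,
                            window_len = 50L, window_step = 10L,
                            fdr_threshold = 0.1, merge_distance = 15L,
                            motif = NULL, n_perm = 20L,
                            grid_max = 1000L, epsilon = 0.02,
                            anchor_replicate = 1L, seed = 1L) {
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 score_min = score_min, fraction_max = fraction_max,
                 p_bg_score = p_bg_score,
                 window_len = as.integer(window_len),
                 window_step = as.integer(window_step),
                 fdr_threshold = fdr_threshold,
                 merge_distance = as.integer(merge_distance),
                 motif = motif %||% (if (!is.null(sim)) sim$motif else "UGCAUG"),
                 n_perm = as.integer(n_perm),
                 grid_max = as.integer(grid_max), epsilon = epsilon,
                 anchor_replicate = as.integer(anchor_replicate),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load pipeline inputs from a fixture bundle directory
#' @noRd
.load_bundle <- function(dir) {
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  annotation <- read_gtf(file.path(dir, "annotation.gtf"))
  snps <- read_bed(file.path(dir, "truth_snps.bed"))
  counts <- list()
  for (f in list.files(dir, pattern = "^sites_.*\\.tsv$", full.names = TRUE)) {
    key <- sub("^sites_(.*)\\.tsv$", "\\1", basename(f))
    counts[[key]] <- read_site_counts(f)
  }
  list(genome = genome, annotation = annotation, snps = snps, counts = counts)
}

#' Run the full short-read analysis pipeline
#'
#' Simulates (or loads) per-condition per-replicate site counts, calls and
#' filters edit sites, calls Poisson edit clusters per replicate against a
#' buffer-only background, derives confident clusters for the case and
#' enzyme-only conditions by replicate intersection and buffer subtraction,
#' and evaluates motif enrichment, nearest-motif distances and the editing
#' radius. Parameters, the anchor replicate, seeds and record counts at
#' every stage are logged to standard error; all outputs are written under
#' `config$out_dir` when given and reruns with the same configuration are
#' byte-identical.
#'
#' @param config a [pipeline_config()]
#' @return list with per-stage results: `counts`, `sites`, `clusters`
#'   (per condition/replicate), `confident` (case and enzyme_only),
#'   `motif_hits`, `enrichment`, `distances`, `radius`, `p_bg_score`,
#'   `bg_rates`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  conds <- .conditions()
  if (!is.null(config$input_dir)) {
    bundle <- .load_bundle(config$input_dir)
    genome <- bundle$genome
    annotation <- bundle$annotation
    snps <- bundle$snps
    counts <- list()
    for (cond in conds) {
      keys <- grep(paste0("^", cond, "_rep"), names(bundle$counts), value = TRUE)
      counts[[cond]] <- bundle$counts[sort(keys)]
    }
    n_rep <- length(counts$case)
  } else {
    if (is.null(config$sim)) stop("pipeline needs either sim or input_dir")
    message("run_pipeline: simulating reference (seed ", config$sim$seed, ")")
    reference <- generate_reference(config$sim)
    genome <- reference$genome
    annotation <- reference$annotation
    snps <- reference$truth$snps
    n_rep <- config$sim$n_replicates
    counts <- lapply(setNames(conds, conds), function(cond) {
      setNames(
        lapply(seq_len(n_rep), function(r) {
          simulate_site_counts(reference, config$sim, cond, r)
        }),
        paste0(cond, "_rep", seq_len(n_rep))
      )
    })
  }

  ## scoring background: global buffer-only edit fraction
  p_bg_score <- if (length(counts$buffer_only)) {
    global_edit_fraction(counts$buffer_only)
  } else {
    config$p_bg_score
  }
  message(sprintf("run_pipeline: scoring background = %.3g", p_bg_score))

  ## edit-site calling and filtering
  sites <- lapply(counts, function(cc) {
    lapply(cc, function(tab) {
      called <- call_edit_sites(tab, p_bg_score)
      filtered <- filter_edit_sites(called, snps,
                                    score_min = config$score_min,
                                    fraction_max = config$fraction_max)
      message(sprintf("run_pipeline: %d candidate -> %d filtered edit sites",
                      nrow(called), nrow(filtered)))
      filtered
    })
  })

  ## background rates from the buffer-only control (artifact baseline)
  bg_rates <- estimate_background_rate(sites$buffer_only, counts$buffer_only,
                                       annotation)
  model <- cluster_model(window_len = config$window_len,
                         window_step = config$window_step,
                         fdr_threshold = config$fdr_threshold,
                         merge_distance = config$merge_distance,
                         p_bg = bg_rates)

  clusters <- lapply(setNames(conds, conds), function(cond) {
    lapply(setNames(names(sites[[cond]]), names(sites[[cond]])), function(key) {
      cl <- call_edit_clusters(sites[[cond]][[key]], counts[[cond]][[key]],
                               annotation, model)
      message(sprintf("run_pipeline: %s -> %d clusters", key, nrow(cl)))
      cl
    })
  })

  ## confident clusters: intersect replicates, subtract buffer-only
  anchor_order <- function(sets) {
    idx <- c(config$anchor_replicate,
             setdiff(seq_along(sets), config$anchor_replicate))
    sets[idx]
  }
  buffer_union <- clusters$buffer_only
  confident <- list(
    case = confident_clusters(anchor_order(clusters$case), buffer_union),
    enzyme_only = confident_clusters(anchor_order(clusters$enzyme_only),
                                     buffer_union)
  )
  message(sprintf("run_pipeline: confident clusters case=%d enzyme_only=%d",
                  nrow(confident$case), nrow(confident$enzyme_only)))

  ## enrichment stage
  hits <- scan_motif(genome, annotation, config$motif)
  enr <- list()
  dists <- list()
  for (cond in c("case", "enzyme_only")) {
    cl <- confident[[cond]]
    if (nrow(cl)) {
      enr[[cond]] <- motif_enrichment(cl, hits, annotation,
                                      n_perm = config$n_perm,
                                      seed = config$seed)
      dists[[cond]] <- nearest_feature_distance(cl, hits)
    } else {
      message("run_pipeline: no confident clusters for ", cond,
              "; enrichment skipped")
    }
  }

  ## edit radius from per-site nearest-motif distances
  site_iv <- function(s) {
    data.frame(chrom = s$chrom, start0 = s$pos0, end0 = s$pos0 + 1L,
               strand = s$strand, stringsAsFactors = FALSE)
  }
  case_site_d <- nearest_feature_distance(site_iv(sites$case[[1]]), hits)
  enz_site_d <- nearest_feature_distance(site_iv(sites$enzyme_only[[1]]), hits)
  radius <- edit_radius(case_site_d, enz_site_d,
                        grid_max = config$grid_max, epsilon = config$epsilon)
  message("run_pipeline: edit radius estimate = ", radius, " nt")

  result <- list(counts = counts, sites = sites, clusters = clusters,
                 confident = confident, motif_hits = hits,
                 enrichment = enr,
                 distances = dists,
                 site_distances = list(case = case_site_d,
                                       enzyme_only = enz_site_d),
                 radius = radius, p_bg_score = p_bg_score,
                 bg_rates = bg_rates, annotation = annotation,
                 genome = genome)

  if (!is.null(config$out_dir)) .write_pipeline_outputs(result, config)
  result
}

#' @noRd
.write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir
  for (cond in names(result$clusters)) {
    for (key in names(result$clusters[[cond]])) {
      cl <- result$clusters[[cond]][[key]]
      write_bed(cl, file.path(od, paste0("clusters_", key, ".bed")),
                extra_cols = c("p_value", "q_value"))
      write.table(result$sites[[cond]][[key]],
                  file.path(od, paste0("sites_", key, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  for (cond in names(result$confident)) {
    write_bed(result$confident[[cond]],
              file.path(od, paste0("confident_", cond, ".bed")),
              extra_cols = c("p_value", "q_value"))
  }
  enr_rows <- do.call(rbind, lapply(names(result$enrichment), function(cond) {
    e <- result$enrichment[[cond]]
    data.frame(condition = cond, observed = e$observed_fraction,
               perm_mean = mean(e$permuted_fractions),
               perm_sd = sd(e$permuted_fractions),
               z = e$z_score, enrichment = e$enrichment,
               n_perm = e$n_perm, stringsAsFactors = FALSE)
  }))
  if (!is.null(enr_rows)) {
    write.table(enr_rows, file.path(od, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (cond in names(result$distances)) {
    write.table(data.frame(distance = result$distances[[cond]]),
                file.path(od, paste0("distances_", cond, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(data.frame(radius = result$radius),
              file.path(od, "edit_radius.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(od)
}
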
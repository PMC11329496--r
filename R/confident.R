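#' Strand-aware replicate intersection of cluster sets
#'
#' Returns the clusters of the first (anchor) set that have at least 1 nt of
#' same-strand overlap with at least one cluster in every other set, applied
#' successively (bedtools `intersect -wa -u -s` semantics). Intervals are
#' reported unmodified. The result depends on which replicate anchors the
#' chain, so the anchor is logged.
#'
#' @param cluster_sets list of >= 2 cluster data.frames; the first is the
#'   anchor
#' @return subset of the anchor set
#' @export
intersect_replicates <- function(cluster_sets) {
  if (length(cluster_sets) < 2L) {
    stop("replicate intersection needs at least 2 cluster sets")
  }
  anchor <- cluster_sets[[1L]]
  nm <- names(cluster_sets)[1L] %||% "set 1"
  message("intersect_replicates: anchor replicate = ", nm,
          " (", nrow(anchor), " clusters)")
  if (!nrow(anchor)) return(anchor)
  keep <- rep(TRUE, nrow(anchor))
  for (other in cluster_sets[-1L]) {
    if (!nrow(other)) {
      keep[] <- FALSE
      break
    }
    hits <- .overlap_hits(anchor, other)
    keep <- keep & seq_len(nrow(anchor)) %in% S4Vectors::queryHits(hits)
  }
  out <- anchor[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtract control clusters (whole-interval removal)
#'
#' Removes every cluster having at least 1 nt of same-strand overlap with any
#' control cluster (bedtools `subtract -A`-like): whole clusters are dropped,
#' never trimmed into fragments. The survivors are the confident edit
#' clusters.
#'
#' @param clusters cluster data.frame (typically from
#'   [intersect_replicates()])
#' @param control_sets a control cluster data.frame or list of them
#' @return subset of `clusters`
#' @export
subtract_control <- function(clusters, control_sets) {
  if (is.data.frame(control_sets)) control_sets <- list(control_sets)
  if (!nrow(clusters)) return(clusters)
  keep <- rep(TRUE, nrow(clusters))
  for (ctrl in control_sets) {
    if (!nrow(ctrl)) next
    hits <- .overlap_hits(clusters, ctrl)
    keep[unique(S4Vectors::queryHits(hits))] <- FALSE
  }
  out <- clusters[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confident edit clusters: intersect replicates, subtract controls
#'
#' @param replicate_sets list of per-replicate cluster sets (anchor first)
#' @param control_sets control cluster set(s); `NULL` skips subtraction
#' @return confident cluster data.frame
#' @export
confident_clusters <- function(replicate_sets, control_sets = NULL) {
  res <- intersect_replicates(replicate_sets)
  if (!is.null(control_sets)) res <- subtract_control(res, control_sets)
  res
}
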
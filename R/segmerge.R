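#' Cluster axonal ROI segments by trace correlation
#'
#' Axonal segments belonging to one cell can appear as disconnected ROIs.
#' Pairs whose raw full-session traces have Pearson correlation above the
#' threshold are linked, and connected components of the resulting graph
#' (single linkage) define putative single axons.
#'
#' Zero-variance traces have no defined correlation; such segments are
#' dropped from the partition with a warning.
#'
#' @param segments list of ROI segments (each with `segment_id`, `raw_trace`).
#' @param threshold correlation threshold; segments correlating strictly above
#'   it are merged. Default 0.8.
#' @return a `merge_partition`: list with `clusters` (list of integer vectors
#'   of segment indices), `segment_ids`, `correlations` (symmetric matrix) and
#'   `threshold`.
#' @export
correlation_cluster <- function(segments, threshold = 0.8) {
  if (length(segments) < 1) stop("need at least one segment", call. = FALSE)
  traces <- vapply(segments, function(s) as.numeric(s$raw_trace),
                   numeric(length(segments[[1]]$raw_trace)))
  if (nrow(traces) < 2) stop("traces must have at least 2 frames", call. = FALSE)
  ids <- vapply(segments, function(s) as.character(s$segment_id), character(1))

  keep <- apply(traces, 2, stats::sd) > 0
  if (!all(keep)) {
    warning(sprintf("excluding %d zero-variance segment(s): %s",
                    sum(!keep), paste(ids[!keep], collapse = ", ")))
  }
  idx <- which(keep)
  cmat <- matrix(NA_real_, length(segments), length(segments),
                 dimnames = list(ids, ids))
  if (length(idx) > 0) cmat[idx, idx] <- stats::cor(traces[, idx, drop = FALSE])

  # Union-find over edges with correlation > threshold.
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (length(idx) > 1) {
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in seq(i + 1, length(idx))) {
        if (cmat[idx[i], idx[j]] > threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  clusters <- unname(split(idx, roots))
  clusters <- clusters[order(vapply(clusters, min, integer(1)))]
  structure(list(clusters = clusters, segment_ids = ids,
                 correlations = cmat, threshold = threshold),
            class = "merge_partition")
}

#' Merge clustered segments into single-axon traces
#'
#' Within each cluster, raw traces are averaged weighted by ROI pixel counts,
#' and the neuropil signal — each segment's neuropil trace scaled by its
#' estimated coefficient — is subtracted using the same pixel-based weights:
#' `merged = sum(w_i raw_i) - sum(w_i c_i neuropil_i)` with
#' `w_i = pixels_i / sum(pixels)`.
#'
#' @param segments list of ROI segments (`pixel_mask`, `raw_trace`,
#'   `neuropil_trace`, `neuropil_coefficient`).
#' @param partition a `merge_partition` from [correlation_cluster()].
#' @return list of merged axons, each with `axon_id`, `segment_ids`,
#'   `segment_indices`, `pixel_mask` (union), `total_pixels`, `merged_trace`.
#' @export
merge_segments <- function(segments, partition) {
  stopifnot(inherits(partition, "merge_partition"))
  lapply(seq_along(partition$clusters), function(ci) {
    members <- partition$clusters[[ci]]
    if (length(members) == 0) stop("empty cluster", call. = FALSE)
    npx <- vapply(members, function(i) nrow(segments[[i]]$pixel_mask), numeric(1))
    w <- npx / sum(npx)
    raw <- Reduce(`+`, Map(function(i, wi) wi * segments[[i]]$raw_trace,
                           members, w))
    np <- Reduce(`+`, Map(function(i, wi) {
      wi * segments[[i]]$neuropil_coefficient * segments[[i]]$neuropil_trace
    }, members, w))
    list(axon_id = ci,
         segment_ids = partition$segment_ids[members],
         segment_indices = members,
         pixel_mask = unique(do.call(rbind, lapply(members, function(i)
           segments[[i]]$pixel_mask))),
         total_pixels = sum(npx),
         merged_trace = raw - np)
  })
}
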
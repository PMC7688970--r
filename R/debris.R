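#' Select the UMI threshold that retains more than the expected cell count
#'
#' Scans thresholds on a fixed UMI grid (default step 50, starting at 0)
#' and returns the largest threshold `t` such that strictly more than
#' `expected_cells` barcodes have total UMI >= `t`. Barcodes below the
#' returned threshold are discarded before clustering.
#'
#' @param counts Barcodes x genes count matrix.
#' @param expected_cells Expected number of recovered cells (the study-scale
#'   default used on real data is 15000).
#' @param step UMI grid step.
#' @return List with `threshold` and logical `retained` per barcode.
#' @export
select_umi_threshold <- function(counts, expected_cells, step = 50) {
  totals <- Matrix::rowSums(counts)
  if (length(totals) < max(expected_cells, 1))
    .cb_stop("fewer barcodes than expected_cells", "capblood_param_error")
  grid <- seq(0, max(totals), by = step)
  n_at <- vapply(grid, function(t) sum(totals >= t), numeric(1))
  ok <- grid[n_at > expected_cells]
  threshold <- if (length(ok)) max(ok) else 0
  list(threshold = threshold, retained = totals >= threshold)
}

#' Cluster retained barcodes in PCA space of the log-transformed matrix
#'
#' PCA is computed on `log(raw counts + 1)` (the visualization transform at
#' unit scale, since debris removal precedes normalization), followed by
#' agglomerative (Ward) clustering. The number of clusters is chosen over
#' `k_range` by the mean silhouette width: maximized by default, or
#' minimized when `silhouette = "minimize"` (both directions are exposed;
#' see the package vignette for why).
#'
#' @param counts Retained barcodes x genes count matrix.
#' @param k_range Candidate numbers of clusters (default `6:15`).
#' @param n_pcs Number of principal components (default 20).
#' @param silhouette `"maximize"` (default) or `"minimize"`.
#' @return List with `labels` (integer cluster per barcode), `k`,
#'   `silhouette_width` per candidate k, and `degenerate` flag (all
#'   silhouette widths equal, e.g. duplicated points; `k` is then the
#'   smallest candidate and should not be interpreted).
#' @export
cluster_retained <- function(counts, k_range = 6:15, n_pcs = 20,
                             silhouette = c("maximize", "minimize")) {
  silhouette <- match.arg(silhouette)
  if (min(k_range) < 2)
    .cb_stop("k_range minimum must be >= 2", "capblood_param_error")
  if (nrow(counts) < max(k_range) + 1)
    .cb_stop("need more barcodes than max(k_range)", "capblood_param_error")
  x <- log1p(as.matrix(counts))
  n_pcs <- min(n_pcs, nrow(x) - 1, ncol(x))
  pcs <- prcomp(x, rank. = n_pcs, center = TRUE, scale. = FALSE)$x
  d <- dist(pcs)
  hc <- hclust(d, method = "ward.D2")
  widths <- vapply(k_range, function(k) {
    lab <- cutree(hc, k)
    if (length(unique(lab)) < 2) return(NA_real_)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  degenerate <- all(is.na(widths)) ||
    (length(widths) > 1L && length(unique(round(widths, 12))) == 1L)
  if (degenerate) {
    warning("silhouette widths degenerate across k_range; ",
            "returning smallest k")
    k <- k_range[1]
  } else {
    k <- k_range[if (silhouette == "maximize") which.max(widths)
                 else which.min(widths)]
  }
  list(labels = setNames(cutree(hc, k), rownames(counts)), k = k,
       silhouette_width = setNames(widths, k_range), degenerate = degenerate)
}

#' Barcode dropoff traces per cluster
#'
#' For each cluster, counts the barcodes remaining when the cluster is
#' thresholded at every UMI value on a grid from 0 to the maximum barcode
#' total, in increments of `step`. The normalized trace divides by cluster
#' size, so every trace starts at 1 and is non-increasing.
#'
#' @param counts Barcodes x genes count matrix (retained barcodes).
#' @param labels Integer cluster labels from [cluster_retained()].
#' @param step UMI grid step.
#' @return List of class `dropoff_traces`: `thresholds`, and per-cluster
#'   `remaining` and `normalized` matrices (clusters x thresholds). Empty
#'   clusters are excluded with a warning.
#' @export
compute_dropoff_traces <- function(counts, labels, step = 50) {
  totals <- Matrix::rowSums(counts)
  # grid extends one step past the largest total so every trace reaches 0
  grid <- seq(0, step * (floor(max(totals) / step) + 1), by = step)
  ids <- sort(unique(labels))
  sizes <- table(factor(labels, levels = ids))
  if (any(sizes == 0)) {
    warning("empty cluster(s) excluded from traces")
    ids <- ids[sizes > 0]
  }
  remaining <- t(vapply(ids, function(cl) {
    tot <- sort(totals[labels == cl])
    # remaining at t = #{totals > t}
    length(tot) - findInterval(grid, tot)
  }, numeric(length(grid))))
  dimnames(remaining) <- list(ids, grid)
  structure(list(thresholds = grid, remaining = remaining,
                 normalized = remaining / as.numeric(table(labels)[as.character(ids)])),
            class = "dropoff_traces")
}

#' Classify clusters as cells or debris from their dropoff traces
#'
#' The normalized traces are split into two groups by agglomerative
#' clustering (average linkage, which unlike Ward admits a singleton
#' debris group when only one cluster shows fast dropoff); the group with
#' the smaller mean area under the normalized trace (i.e. the faster
#' barcode dropoff) is labeled debris. When both
#' groups have identical mean area, the group containing the smallest
#' cluster id is labeled debris (deterministic tie-break).
#'
#' @param traces A `dropoff_traces` object.
#' @return Named character vector, `"cells"` or `"debris"` per cluster id.
#'   If all traces are identical no debris is called (with a warning).
#' @export
classify_trace_groups <- function(traces) {
  z <- traces$normalized
  if (nrow(z) < 2)
    .cb_stop("need at least two cluster traces", "capblood_param_error")
  if (all(apply(z, 2, function(col) length(unique(col)) == 1L))) {
    warning("all dropoff traces identical; no debris called")
    return(setNames(rep("cells", nrow(z)), rownames(z)))
  }
  grp <- cutree(hclust(dist(z), method = "average"), k = 2)
  auc <- rowMeans(z)
  mean_auc <- tapply(auc, grp, mean)
  debris_grp <- if (abs(diff(mean_auc)) < 1e-12) {
    grp[[which.min(as.integer(rownames(z)))]]
  } else as.integer(names(which.min(mean_auc)))
  setNames(ifelse(grp == debris_grp, "debris", "cells"), rownames(z))
}

#' Full debris-removal call for a raw barcode matrix
#'
#' Runs the threshold selection, PCA + agglomerative clustering of retained
#' barcodes, per-cluster dropoff traces, and the two-way trace
#' classification, and assembles a per-barcode call.
#'
#' @param counts Raw barcodes x genes count matrix (all droplets).
#' @param expected_cells Expected number of recovered cells.
#' @param step UMI grid step for both thresholding and traces.
#' @param k_range,n_pcs,silhouette Passed to [cluster_retained()].
#' @return List of class `debris_call`: `call` (factor per barcode with
#'   levels `below_threshold`, `debris`, `keep`), `threshold`, `k`,
#'   `cluster_labels`, `cluster_class`, `traces`.
#' @export
remove_debris <- function(counts, expected_cells, step = 50,
                          k_range = 6:15, n_pcs = 20,
                          silhouette = c("maximize", "minimize")) {
  thr <- select_umi_threshold(counts, expected_cells, step)
  kept <- counts[thr$retained, , drop = FALSE]
  cl <- cluster_retained(kept, k_range, n_pcs, match.arg(silhouette))
  traces <- compute_dropoff_traces(kept, cl$labels, step)
  classes <- classify_trace_groups(traces)
  call <- rep("below_threshold", nrow(counts))
  names(call) <- rownames(counts)
  call[names(cl$labels)] <-
    ifelse(classes[as.character(cl$labels)] == "debris", "debris", "keep")
  call <- factor(call, levels = c("below_threshold", "debris", "keep"))
  names(call) <- rownames(counts)
  structure(list(
    call = call,
    threshold = thr$threshold, k = cl$k, cluster_labels = cl$labels,
    cluster_class = classes, traces = traces), class = "debris_call")
}

#' @export
print.debris_call <- function(x, ...) {
  cat("debris_call: threshold", x$threshold, "| k =", x$k, "|",
      paste(names(table(x$call)), table(x$call), collapse = ", "), "\n")
  invisible(x)
}
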
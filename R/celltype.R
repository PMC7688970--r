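#' Default marker panel for cluster annotation
#'
#' @return Named list mapping cell type to marker gene symbols (the same
#'   canonical PBMC panel the simulator uses; user-overridable).
#' @export
default_marker_panel <- function() {
  specs <- default_cell_types()
  setNames(lapply(specs, `[[`, "marker_genes"),
           vapply(specs, `[[`, character(1), "name"))
}

#' Embed cells in a low-dimensional latent space
#'
#' The default embedding is PCA of the visualization-transformed expression
#' fractions. A precomputed external latent space (e.g. from a trained
#' autoencoder, which can also encode batch correction) can be substituted
#' via `external`; its rows must match the barcodes exactly.
#'
#' @param fractions Barcodes x genes normalized fraction matrix.
#' @param d Embedding dimensionality (default 10).
#' @param external Optional numeric matrix (barcodes x dims) with rownames;
#'   used verbatim instead of PCA.
#' @return Object of class `cell_embedding`: list with `coordinates`
#'   (barcodes x d) and `method`.
#' @export
embed_cells <- function(fractions, d = 10, external = NULL) {
  if (!is.null(external)) {
    if (!setequal(rownames(external), rownames(fractions)))
      .cb_stop("external embedding barcodes do not match matrix",
               "capblood_param_error")
    coords <- as.matrix(external)[rownames(fractions), , drop = FALSE]
    return(structure(list(coordinates = coords, method = "external"),
                     class = "cell_embedding"))
  }
  if (nrow(fractions) < d + 1)
    .cb_stop("need at least d+1 cells", "capblood_param_error")
  x <- viz_transform(as.matrix(fractions))
  d <- min(d, ncol(x))
  coords <- prcomp(x, rank. = d, center = TRUE, scale. = FALSE)$x
  rownames(coords) <- rownames(fractions)
  structure(list(coordinates = coords, method = "internal-PCA"),
            class = "cell_embedding")
}

#' Score a cluster's marker panel annotation
#'
#' For each cell type in the panel, computes the mean over panel genes of
#' the cluster's mean normalized expression, with each gene standardized
#' across clusters (so highly expressed genes do not dominate). The
#' annotation of a cluster is the argmax type; exact ties resolve to the
#' earliest type in panel order with a warning.
#'
#' @param cluster_means Clusters x genes matrix of mean normalized
#'   expression per cluster.
#' @param panel Named list mapping cell type to marker genes.
#' @return Clusters x types score matrix.
#' @export
score_cluster_annotation <- function(cluster_means, panel) {
  genes <- colnames(cluster_means)
  zs <- scale(cluster_means)        # standardize each gene across clusters
  zs[is.nan(zs)] <- 0               # constant genes carry no signal
  scores <- sapply(panel, function(mk) {
    mk <- intersect(mk, genes)
    if (!length(mk)) return(rep(NA_real_, nrow(cluster_means)))
    rowMeans(zs[, mk, drop = FALSE])
  })
  if (!is.matrix(scores))
    scores <- matrix(scores, nrow = nrow(cluster_means),
                     dimnames = list(NULL, names(panel)))
  rownames(scores) <- rownames(cluster_means)
  scores
}

.annotate_clusters <- function(fractions, labels, panel) {
  ids <- sort(unique(labels))
  cm <- t(vapply(ids, function(cl)
    Matrix::colMeans(fractions[labels == cl, , drop = FALSE]),
    numeric(ncol(fractions))))
  rownames(cm) <- ids
  scores <- score_cluster_annotation(cm, panel)
  ann <- apply(scores, 1, function(s) {
    if (all(is.na(s))) return(NA_character_)
    top <- which(s == max(s, na.rm = TRUE))
    if (length(top) > 1)
      warning("tied annotation scores; using panel order")
    names(panel)[top[1]]
  })
  setNames(ann, ids)
}

#' Cluster cells and annotate clusters with cell types
#'
#' Agglomerative (Ward) clustering of the embedding, with the number of
#' clusters incremented from `k_min`: at each k every cluster is annotated
#' by its argmax marker-panel score, and the search stops at the first k at
#' which every panel type is the annotation of at least one cluster
#' (operationalizing "all types separable"). Clusters sharing an annotation
#' are merged into a single cell type. If no k in the range succeeds, the k
#' annotating the most distinct types is returned with a warning.
#'
#' @param embedding A [embed_cells()] result.
#' @param fractions Barcodes x genes fraction matrix (for marker scoring).
#' @param panel Named list mapping cell type to marker genes.
#' @param k_min,k_max Cluster-number search range (defaults 13 and 15).
#' @return List of class `cell_typing`: `cell_type` (named character per
#'   barcode), `k`, `cluster_labels`, `cluster_annotation`, `found_all`.
#' @export
cluster_cells <- function(embedding, fractions, panel = default_marker_panel(),
                          k_min = 13, k_max = 15) {
  coords <- embedding$coordinates
  if (nrow(coords) <= k_max)
    .cb_stop("fewer cells than k_max", "capblood_param_error")
  hc <- hclust(dist(coords), method = "ward.D2")
  best <- NULL
  for (k in k_min:k_max) {
    labels <- cutree(hc, k)
    ann <- .annotate_clusters(fractions, labels, panel)
    n_found <- length(intersect(names(panel), ann))
    if (is.null(best) || n_found > best$n_found)
      best <- list(k = k, labels = labels, ann = ann, n_found = n_found)
    if (n_found == length(panel)) break
  }
  found_all <- best$n_found == length(panel)
  if (!found_all)
    warning("not all panel types separable in k range; using k = ", best$k,
            " with ", best$n_found, " of ", length(panel), " types")
  cell_type <- setNames(unname(best$ann[as.character(best$labels)]),
                        names(best$labels))
  structure(list(cell_type = cell_type, k = best$k,
                 cluster_labels = best$labels,
                 cluster_annotation = best$ann, found_all = found_all),
            class = "cell_typing")
}

#' @export
print.cell_typing <- function(x, ...) {
  cat("cell_typing: k =", x$k, "->",
      length(unique(stats::na.omit(x$cell_type))), "cell types over",
      length(x$cell_type), "cells\n")
  print(table(x$cell_type))
  invisible(x)
}
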
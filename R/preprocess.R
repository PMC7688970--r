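#' Pre-typing gene filter: discard genes never reaching a minimum count
#'
#' Retains exactly the genes whose maximum count in any single cell is at
#' least `min_max_count` (default 3). Applied before cell typing.
#'
#' @param counts Barcodes x genes count matrix.
#' @param min_max_count Minimum per-cell maximum count to retain a gene.
#' @return The filtered count matrix.
#' @export
filter_genes_pre <- function(counts, min_max_count = 3) {
  if (ncol(counts) == 0 || nrow(counts) == 0)
    return(counts[, Matrix::colSums(counts) >= min_max_count, drop = FALSE])
  cmax <- .col_max_sparse(counts)
  counts[, cmax >= min_max_count, drop = FALSE]
}

# column maxima of a sparse matrix without densifying
.col_max_sparse <- function(m) {
  m <- as(m, "CsparseMatrix")
  nz <- diff(m@p)
  out <- numeric(ncol(m))
  if (length(m@x))
    out[nz > 0] <- vapply(which(nz > 0), function(j) {
      max(m@x[(m@p[j] + 1):m@p[j + 1]])
    }, numeric(1))
  out
}

#' Post-typing gene filter: require presence in a cell type
#'
#' Retains genes with a nonzero count in at least `min_fraction` of the
#' cells of one or more cell types. Applied after cell typing; untyped and
#' debris cells are ignored. Types with very few cells make the fraction
#' denominator unstable; types of fewer than 10 cells are reported.
#'
#' @param counts Barcodes x genes count matrix.
#' @param cell_types Character vector of per-barcode cell type labels
#'   (NA = untyped), aligned with `rownames(counts)`.
#' @param min_fraction Minimum expressing-cell fraction (default 0.10).
#' @return The filtered count matrix.
#' @export
filter_genes_post <- function(counts, cell_types, min_fraction = 0.10) {
  stopifnot(length(cell_types) == nrow(counts))
  typed <- !is.na(cell_types)
  if (!any(typed)) .cb_stop("no typed cells", "capblood_param_error")
  types <- unique(cell_types[typed])
  small <- types[table(cell_types[typed])[types] < 10]
  if (length(small))
    message("small-denominator cell type(s) in post filter: ",
            paste(small, collapse = ", "))
  keep <- rep(FALSE, ncol(counts))
  for (ct in types) {
    sel <- which(typed & cell_types == ct)
    frac <- Matrix::colSums(counts[sel, , drop = FALSE] > 0) / length(sel)
    keep <- keep | frac >= min_fraction
  }
  counts[, keep, drop = FALSE]
}

#' Per-cell fraction normalization
#'
#' Divides each gene's count in a cell by the cell's total count, so every
#' row of the result sums to 1. Barcodes with zero total counts are dropped
#' with a warning.
#'
#' @param counts Barcodes x genes count matrix.
#' @return Sparse row-stochastic matrix of expression fractions.
#' @export
normalize_fractions <- function(counts) {
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " zero-count barcode(s) dropped")
    counts <- counts[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  counts / totals
}

#' Visualization transform of expression fractions
#'
#' Computes `log(scale * f + 1)` (natural log, default scale 5000). Used
#' for display and as the input convention for the typing embedding; never
#' as the unit of any statistical test.
#'
#' @param fractions Matrix of expression fractions.
#' @param scale Constant multiplier before the log.
#' @return Transformed matrix (same shape).
#' @export
viz_transform <- function(fractions, scale = 5000) {
  log1p(scale * fractions)
}
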
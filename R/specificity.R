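#' Subject-specificity ANOVA per gene and cell type
#'
#' For each cell type and gene, forms one group per subject containing that
#' subject's per-sample pseudobulk means and applies a one-way ANOVA.
#' Benjamini-Hochberg correction is applied jointly across the gene x
#' cell-type grid; the per-gene plotting statistic is `log2(F)` at the
#' minimum-p cell type.
#'
#' @param tensor A [build_tensor()] result (raw means, not renormalized).
#' @param fdr FDR level (default 0.05).
#' @param min_samples Minimum unmasked samples per subject group
#'   (default 2).
#' @return Object of class `specificity_result` with `axis = "subject"`:
#'   `tests` (`gene`, `cell_type`, `F`, `log2F`, `p`, `q`, `significant`,
#'   `degenerate`), `per_gene`, `fdr`.
#' @export
subject_specificity_test <- function(tensor, fdr = 0.05, min_samples = 2) {
  g <- tensor$groups
  out <- list()
  for (ct in unique(g$cell_type)) {
    rows <- which(g$cell_type == ct & !is.na(tensor$mu[, 1]))
    grp <- split(rows, g$subject[rows])
    grp <- grp[vapply(grp, length, integer(1)) >= min_samples]
    if (length(grp) < 2) {
      warning("cell type ", ct, " has fewer than two subjects with >= ",
              min_samples, " samples; skipped")
      next
    }
    av <- col_oneway_anova(lapply(grp, function(r)
      tensor$mu[r, , drop = FALSE]))
    out[[ct]] <- data.frame(
      gene = tensor$genes, cell_type = ct, F = av$F,
      p = av$p, degenerate = av$degenerate,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(out))
    .cb_stop("no cell type supports the subject ANOVA",
             "capblood_param_error")
  .finish_specificity(out, tensor$genes, fdr, axis = "subject")
}

#' Cell-type-specificity ANOVA per gene
#'
#' For each gene, forms one group per cell type containing the per-sample
#' pseudobulk means of that type (pooled across subjects) and applies a
#' one-way ANOVA. A single test per gene; BH-corrected across genes.
#'
#' @inheritParams subject_specificity_test
#' @param min_samples Minimum unmasked observations per cell-type group.
#' @return A `specificity_result` with `axis = "cell_type"` (the
#'   `cell_type` column is `"ALL"`).
#' @export
celltype_specificity_test <- function(tensor, fdr = 0.05, min_samples = 2) {
  g <- tensor$groups
  rows <- which(!is.na(tensor$mu[, 1]))
  grp <- split(rows, g$cell_type[rows])
  grp <- grp[vapply(grp, length, integer(1)) >= min_samples]
  if (length(grp) < 2)
    .cb_stop("need at least two cell types with enough samples",
             "capblood_param_error")
  av <- col_oneway_anova(lapply(grp, function(r)
    tensor$mu[r, , drop = FALSE]))
  out <- list(ALL = data.frame(
    gene = tensor$genes, cell_type = "ALL", F = av$F, p = av$p,
    degenerate = av$degenerate, stringsAsFactors = FALSE, row.names = NULL))
  .finish_specificity(out, tensor$genes, fdr, axis = "cell_type")
}

.finish_specificity <- function(out, genes, fdr, axis) {
  tests <- do.call(rbind, out); rownames(tests) <- NULL
  bh <- bh_correct(tests$p, fdr)
  tests$q <- bh$q
  tests$significant <- bh$reject
  tests$log2F <- log2(tests$F)
  o <- order(tests$p)
  per_gene <- tests[o[!duplicated(tests$gene[o])], , drop = FALSE]
  per_gene <- per_gene[match(genes, per_gene$gene), , drop = FALSE]
  rownames(per_gene) <- NULL
  structure(list(tests = tests, per_gene = per_gene, fdr = fdr,
                 axis = axis),
            class = "specificity_result")
}

#' Compare cell-type composition between two cohorts
#'
#' Per cell type, a two-sided classical two-sample t-test of per-sample
#' composition fractions between cohorts, BH-corrected across cell types
#' (the cross-cohort composition comparison display). Types present in
#' only one cohort are skipped with a warning.
#'
#' @param cohort_a,cohort_b Data.frames of per-sample fractions, one column
#'   per cell type (e.g. from [sample_celltype_fractions()], cell-type
#'   columns only), each with at least 2 rows.
#' @param fdr FDR level for the per-type significance flags (default 0.05).
#' @return Data.frame `cell_type`, `mean_a`, `mean_b`, `t`, `p`, `q`,
#'   `significant`.
#' @export
compare_cohort_fractions <- function(cohort_a, cohort_b, fdr = 0.05) {
  num_a <- vapply(cohort_a, is.numeric, logical(1))
  num_b <- vapply(cohort_b, is.numeric, logical(1))
  a <- as.matrix(cohort_a[, num_a, drop = FALSE])
  b <- as.matrix(cohort_b[, num_b, drop = FALSE])
  if (nrow(a) < 2 || nrow(b) < 2)
    .cb_stop("each cohort needs >= 2 samples", "capblood_param_error")
  shared <- intersect(colnames(a), colnames(b))
  only <- setdiff(union(colnames(a), colnames(b)), shared)
  if (length(only))
    warning("cell type(s) present in one cohort only skipped: ",
            paste(only, collapse = ", "))
  if (!length(shared))
    .cb_stop("no shared cell types", "capblood_param_error")
  tt <- col_t_pooled(a[, shared, drop = FALSE], b[, shared, drop = FALSE])
  bh <- bh_correct(tt$p, fdr)
  data.frame(cell_type = shared, mean_a = tt$mean1, mean_b = tt$mean2,
             t = tt$t, p = tt$p, q = bh$q, significant = bh$reject,
             stringsAsFactors = FALSE, row.names = NULL)
}
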
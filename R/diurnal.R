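#' Within-subject AM/PM renormalization of the pseudobulk tensor
#'
#' For every (gene, subject, cell type), subtracts the equally weighted
#' mean of the subject's AM-session and PM-session means:
#' `mu' = mu - (mean(AM mu) + mean(PM mu)) / 2`, each class mean taken over
#' that subject's available (unmasked) sessions. This removes subject
#' baseline differences while weighting the two session classes equally
#' regardless of how many sessions each class has. Subject-cell-type
#' combinations lacking an unmasked session in either class are dropped
#' from testing (with a warning).
#'
#' @param tensor A [build_tensor()] result.
#' @return A `pseudobulk_tensor` of renormalized values `mu'` (groups
#'   failing the AM+PM requirement removed).
#' @export
renormalize_eq1 <- function(tensor) {
  g <- tensor$groups
  mu <- tensor$mu
  keep <- rep(TRUE, nrow(g))
  dropped <- character(0)
  for (sc in split(seq_len(nrow(g)),
                   list(g$subject, g$cell_type), drop = TRUE)) {
    rows <- sc[!is.na(mu[sc, 1])]
    am <- rows[g$period[rows] == "AM"]
    pm <- rows[g$period[rows] == "PM"]
    if (!length(am) || !length(pm)) {
      keep[sc] <- FALSE
      dropped <- c(dropped, paste0(g$subject[sc[1]], "/", g$cell_type[sc[1]]))
      next
    }
    keep[setdiff(sc, rows)] <- FALSE
    offset <- (colMeans(mu[am, , drop = FALSE]) +
               colMeans(mu[pm, , drop = FALSE])) / 2
    mu[rows, ] <- sweep(mu[rows, , drop = FALSE], 2, offset)
  }
  if (length(dropped))
    warning("subject/cell-type combination(s) without both AM and PM ",
            "sessions dropped: ", paste(unique(dropped), collapse = ", "))
  structure(list(mu = mu[keep, , drop = FALSE],
                 groups = g[keep, , drop = FALSE],
                 genes = tensor$genes, min_cells = tensor$min_cells,
                 renormalized = TRUE),
            class = "pseudobulk_tensor")
}

#' Diurnal (AM vs PM) gene detection per cell type
#'
#' For every cell type, pools the renormalized per-sample means `mu'`
#' across subjects into an AM group and a PM group and applies a two-tailed
#' classical (pooled-variance) two-sample t-test per gene (Welch's variant
#' available via `welch = TRUE`). Benjamini-Hochberg correction is applied
#' jointly across the full gene x cell-type grid. The per-gene plotting
#' statistic is the signed z (normal quantile of the two-sided p, signed by
#' the AM - PM mean difference) at the cell type with minimum p.
#'
#' @param renorm A [renormalize_eq1()] tensor (of `mu'` values).
#' @param fdr FDR level for the significance flags (default 0.05).
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   test.
#' @param abundance Optional named per-gene abundance (largest percent of
#'   cells of a subpopulation expressing the gene, from
#'   [expression_abundance()]); carried into the result for plotting.
#' @return Object of class `diurnal_result`: `tests` (data.frame `gene`,
#'   `cell_type`, `n_am`, `n_pm`, `mean_am`, `mean_pm`, `mean_diff`, `t`,
#'   `z`, `p`, `q`, `significant`, `degenerate`), `per_gene` (row of
#'   minimum p per gene, plus `abundance`), and `fdr`.
#' @export
diurnal_test <- function(renorm, fdr = 0.05, welch = FALSE,
                         abundance = NULL) {
  g <- renorm$groups
  out <- list()
  for (ct in unique(g$cell_type)) {
    rows <- which(g$cell_type == ct & !is.na(renorm$mu[, 1]))
    am <- rows[g$period[rows] == "AM"]
    pm <- rows[g$period[rows] == "PM"]
    if (length(am) < 2 || length(pm) < 2) {
      warning("cell type ", ct, " lacks >=2 AM and >=2 PM samples; skipped")
      next
    }
    A <- renorm$mu[am, , drop = FALSE]
    B <- renorm$mu[pm, , drop = FALSE]
    tt <- if (welch) col_t_welch(A, B) else col_t_pooled(A, B)
    out[[ct]] <- data.frame(
      gene = renorm$genes, cell_type = ct,
      n_am = length(am), n_pm = length(pm),
      mean_am = tt$mean1, mean_pm = tt$mean2,
      mean_diff = tt$mean1 - tt$mean2,
      t = tt$t, p = tt$p, degenerate = tt$degenerate,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(out))
    .cb_stop("no cell type has enough AM and PM samples",
             "capblood_param_error")
  tests <- do.call(rbind, out); rownames(tests) <- NULL
  bh <- bh_correct(tests$p, fdr)
  tests$q <- bh$q
  tests$significant <- bh$reject
  tests$z <- signed_z(tests$p, tests$mean_diff)
  o <- order(tests$p)                       # stable: ties keep type order
  per_gene <- tests[o[!duplicated(tests$gene[o])], , drop = FALSE]
  per_gene <- per_gene[match(renorm$genes, per_gene$gene), , drop = FALSE]
  rownames(per_gene) <- NULL
  if (!is.null(abundance))
    per_gene$abundance <- unname(abundance[per_gene$gene])
  structure(list(tests = tests, per_gene = per_gene, fdr = fdr),
            class = "diurnal_result")
}

# Welch variant (df by Welch-Satterthwaite); same degenerate conventions
col_t_welch <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- colSums(sweep(A, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(B, 2, m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  zero <- se2 == 0
  eq <- zero & (m1 == m2)
  t[eq] <- 0; p[eq] <- 1
  deg <- zero & !eq
  t[deg] <- sign(m1 - m2)[deg] * Inf
  p[deg] <- .Machine$double.xmin
  list(t = t, p = p, df = df, mean1 = m1, mean2 = m2, degenerate = deg)
}

#' Population-level diurnal test
#'
#' The identical AM vs PM procedure applied to the pooled tensor (all cells
#' collapsed into the single pseudo-type `"ALL"`, see
#' [build_tensor()] with `pooled = TRUE`).
#'
#' @inheritParams diurnal_test
#' @param renorm_pooled Renormalized pooled tensor.
#' @return A `diurnal_result` (single cell type `"ALL"`).
#' @export
population_level_test <- function(renorm_pooled, fdr = 0.05, welch = FALSE,
                                  abundance = NULL) {
  diurnal_test(renorm_pooled, fdr = fdr, welch = welch,
               abundance = abundance)
}

#' Cross-classify per-type and population-level diurnal calls
#'
#' Assigns each gene one of four exclusive classes: `both` (significant in
#' at least one cell type and at population level), `celltype_specific`
#' (types only — genes a population-level analysis would miss), and
#' `population_only_abundance_suspect` (population level only — candidates
#' for cell-type abundance-shift false positives), or `none`.
#'
#' @param celltype_result `diurnal_result` from the per-type test.
#' @param population_result `diurnal_result` from the pooled test.
#' @return Data.frame with `gene`, `class`, `celltypes` (comma-separated
#'   supporting cell types).
#' @export
classify_diurnal <- function(celltype_result, population_result) {
  genes <- union(celltype_result$per_gene$gene,
                 population_result$per_gene$gene)
  sig_ct <- celltype_result$tests[celltype_result$tests$significant, ,
                                  drop = FALSE]
  by_gene <- split(sig_ct$cell_type, sig_ct$gene)
  in_ct <- genes %in% names(by_gene)
  pg <- population_result$per_gene
  in_pop <- genes %in% pg$gene[pg$significant]
  cls <- ifelse(in_ct & in_pop, "both",
         ifelse(in_ct, "celltype_specific",
         ifelse(in_pop, "population_only_abundance_suspect", "none")))
  data.frame(
    gene = genes, class = cls,
    celltypes = vapply(genes, function(gn)
      paste(by_gene[[gn]], collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sample cell-type composition fractions
#'
#' @param annotation Per-barcode annotation (typed, subject-assigned cells
#'   are counted; others ignored).
#' @return Data.frame: one row per (subject, sample), one column per cell
#'   type, entries the fraction of that sample's typed cells. Types absent
#'   from a sample get fraction 0.
#' @export
sample_celltype_fractions <- function(annotation) {
  ann <- annotation[!is.na(annotation$cell_type) &
                    annotation$subject != "unassigned", , drop = FALSE]
  if (!nrow(ann)) .cb_stop("no typed cells", "capblood_param_error")
  tab <- table(paste(ann$subject, ann$sample, sep = "\r"), ann$cell_type)
  frac <- as.matrix(tab / rowSums(tab))
  parts <- do.call(rbind, strsplit(rownames(frac), "\r", fixed = TRUE))
  out <- data.frame(subject = parts[, 1], sample = parts[, 2],
                    stringsAsFactors = FALSE)
  out$period <- sub(".*_", "", out$sample)
  cbind(out, as.data.frame.matrix(frac, stringsAsFactors = FALSE),
        stringsAsFactors = FALSE)
}

#' One-sided test for an AM/PM cell-type abundance shift
#'
#' Computes per-(subject, sample) fractions of cells of the given type and
#' applies a one-sided classical two-sample t-test in the stated direction
#' (`"PM_greater"` tests for an increase of the type's abundance in the
#' afternoon, as for the published B-cell shift).
#'
#' @param annotation Per-barcode annotation with cell types assigned.
#' @param cell_type Cell type whose abundance is tested.
#' @param direction `"PM_greater"` (default) or `"AM_greater"`.
#' @return List with `t`, `p` (one-sided), `mean_am`, `mean_pm`, `n_am`,
#'   `n_pm`.
#' @export
abundance_shift_test <- function(annotation, cell_type,
                                 direction = c("PM_greater", "AM_greater")) {
  direction <- match.arg(direction)
  fr <- sample_celltype_fractions(annotation)
  if (!cell_type %in% names(fr))
    .cb_stop(paste("cell type", cell_type, "not present"),
             "capblood_param_error")
  am <- fr[fr$period == "AM", cell_type]
  pm <- fr[fr$period == "PM", cell_type]
  if (length(am) < 2 || length(pm) < 2)
    .cb_stop("need >=2 AM and >=2 PM samples", "capblood_param_error")
  tt <- col_t_pooled(matrix(am, ncol = 1), matrix(pm, ncol = 1))
  # col_t_pooled tests AM - PM; one-sided p in the requested direction
  p <- if (direction == "PM_greater") pt(tt$t, tt$df)
       else pt(tt$t, tt$df, lower.tail = FALSE)
  list(t = unname(tt$t), p = unname(p), mean_am = mean(am),
       mean_pm = mean(pm), n_am = length(am), n_pm = length(pm))
}

#' Per-gene expression abundance across subpopulations
#'
#' The largest percent of cells of any one cell type with a nonzero count
#' for the gene (the marker-size quantity of the diurnal scatter display).
#'
#' @param counts Barcodes x genes count matrix.
#' @param cell_types Per-barcode cell type labels (NA ignored).
#' @return Named numeric vector (percent, 0-100) per gene.
#' @export
expression_abundance <- function(counts, cell_types) {
  stopifnot(length(cell_types) == nrow(counts))
  types <- unique(cell_types[!is.na(cell_types)])
  best <- rep(0, ncol(counts))
  for (ct in types) {
    sel <- which(!is.na(cell_types) & cell_types == ct)
    frac <- Matrix::colSums(counts[sel, , drop = FALSE] > 0) / length(sel)
    best <- pmax(best, frac)
  }
  setNames(100 * best, colnames(counts))
}
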
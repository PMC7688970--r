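#' Build the pseudobulk mean-expression tensor
#'
#' Computes the mean normalized expression of every gene over the cells of
#' each (subject, cell type, sample) group — the statistic every downstream
#' test runs on. Groups with fewer than `min_cells` cells are masked
#' (stored as `NA`). With `pooled = TRUE` all typed cells collapse into the
#' single pseudo-type `"ALL"`, giving the population-level tensor.
#'
#' @param fractions Barcodes x genes normalized fraction matrix.
#' @param annotation Per-barcode annotation with `barcode`, `subject`,
#'   `sample`, `cell_type` (cells with `"unassigned"` subject or `NA` type
#'   are excluded).
#' @param design A [sample_design()].
#' @param min_cells Minimum cells per group for an unmasked entry
#'   (default 3; set to 1 to reproduce the literal published procedure,
#'   which states no floor).
#' @param pooled Collapse all cell types into `"ALL"`.
#' @return Object of class `pseudobulk_tensor`: list with `mu` (groups x
#'   genes matrix, `NA` where masked), `groups` (data.frame `subject`,
#'   `cell_type`, `sample`, `day`, `period`, `n_cells`), `genes`,
#'   `min_cells`.
#' @export
build_tensor <- function(fractions, annotation, design, min_cells = 3,
                         pooled = FALSE) {
  ann <- annotation[match(rownames(fractions), annotation$barcode), ,
                    drop = FALSE]
  if (pooled) ann$cell_type <- ifelse(is.na(ann$cell_type), NA, "ALL")
  use <- !is.na(ann$cell_type) & !is.na(ann$subject) &
    ann$subject != "unassigned" & !is.na(ann$sample)
  if (!any(use)) .cb_stop("no typed, subject-assigned cells",
                          "capblood_param_error")
  x <- fractions[use, , drop = FALSE]
  key <- interaction(ann$subject[use], ann$cell_type[use], ann$sample[use],
                     sep = "\r", drop = TRUE)
  ind <- sparseMatrix(i = as.integer(key), j = seq_len(nrow(x)), x = 1,
                      dims = c(nlevels(key), nrow(x)))
  n_cells <- as.numeric(Matrix::rowSums(ind))
  mu <- as.matrix(ind %*% x) / n_cells
  parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  groups <- data.frame(subject = parts[, 1], cell_type = parts[, 2],
                       sample = parts[, 3], stringsAsFactors = FALSE)
  si <- match(groups$sample, design$sessions$sample)
  groups$day <- design$sessions$day[si]
  groups$period <- design$sessions$period[si]
  groups$n_cells <- n_cells
  mu[n_cells < min_cells, ] <- NA_real_
  colnames(mu) <- colnames(fractions)

  # order groups by cell type, subject, chronological session
  o <- order(groups$cell_type, groups$subject, si)
  groups <- groups[o, , drop = FALSE]; rownames(groups) <- NULL
  mu <- mu[o, , drop = FALSE]

  dropped <- tapply(groups$n_cells >= min_cells, groups$cell_type, sum) == 0
  if (any(dropped))
    warning("cell type(s) with no unmasked entries: ",
            paste(names(dropped)[dropped], collapse = ", "))
  structure(list(mu = mu, groups = groups, genes = colnames(fractions),
                 min_cells = min_cells),
            class = "pseudobulk_tensor")
}

#' @export
print.pseudobulk_tensor <- function(x, ...) {
  cat("pseudobulk_tensor:", length(x$genes), "genes x", nrow(x$groups),
      "(subject, cell type, sample) groups;",
      sum(is.na(x$mu[, 1])), "masked (min_cells =", x$min_cells, ")\n")
  invisible(x)
}

#' Long-format view of a pseudobulk tensor
#'
#' @param x A `pseudobulk_tensor`.
#' @param ... Unused.
#' @return Data.frame with one row per (gene, subject, cell_type, sample):
#'   columns `gene`, `subject`, `cell_type`, `sample`, `mean`, `n_cells`.
#' @export
as.data.frame.pseudobulk_tensor <- function(x, ...) {
  g <- x$groups[rep(seq_len(nrow(x$groups)), times = length(x$genes)),
                c("subject", "cell_type", "sample", "n_cells")]
  data.frame(gene = rep(x$genes, each = nrow(x$groups)), g,
             mean = as.vector(x$mu), row.names = NULL,
             stringsAsFactors = FALSE)
}
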
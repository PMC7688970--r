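#' Load a pathway database from a GMT file with a category sidecar
#'
#' Reads GMT gene sets (one pathway per line: id, description, member
#' genes) and joins a category annotation from a two-column TSV
#' (`pathway_id`, `category`). Pathways without a category are assigned
#' `"Other"` with a warning. The category regrouping used for
#' immune-focused display (splitting disease pathways into immune /
#' infectious / other, and separating the immune system from other
#' organismal systems) is expressed entirely through this sidecar.
#'
#' @param path GMT file path.
#' @param category_sidecar Optional TSV path with columns `pathway_id`,
#'   `category`.
#' @return Object of class `pathway_db`: list with `pathways` (named list
#'   of gene vectors) and `categories` (named character per pathway).
#' @export
load_gmt <- function(path, category_sidecar = NULL) {
  pw <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(pw)))
    .cb_stop("duplicate pathway id in GMT", "capblood_format_error")
  if (any(!vapply(pw, length, integer(1))))
    .cb_stop("empty gene set in GMT", "capblood_format_error")
  categories <- setNames(rep(NA_character_, length(pw)), names(pw))
  if (!is.null(category_sidecar)) {
    sc <- read.delim(category_sidecar, stringsAsFactors = FALSE)
    categories[sc$pathway_id[sc$pathway_id %in% names(pw)]] <-
      sc$category[sc$pathway_id %in% names(pw)]
  }
  if (any(is.na(categories))) {
    warning(sum(is.na(categories)),
            " pathway(s) without category assigned to 'Other'")
    categories[is.na(categories)] <- "Other"
  }
  structure(list(pathways = pw, categories = categories),
            class = "pathway_db")
}

#' Pathway-multiplicity gene weights
#'
#' Each gene is weighted by the reciprocal of the number of pathways it
#' appears in, normalizing for promiscuous genes. Genes in no pathway are
#' excluded from the enrichment universe.
#'
#' @param db A [load_gmt()] database.
#' @param genes_in_data Optional character vector restricting the universe
#'   to genes present in the expression data.
#' @return Named numeric vector of weights in (0, 1].
#' @export
gene_weights <- function(db, genes_in_data = NULL) {
  counts <- table(unlist(db$pathways, use.names = FALSE))
  w <- 1 / as.numeric(counts)
  names(w) <- names(counts)
  if (!is.null(genes_in_data)) w <- w[names(w) %in% genes_in_data]
  w
}

#' Select the top diurnal and subject-specific genes
#'
#' Takes the union of the `n` smallest-p genes of the diurnal per-gene
#' ranking and the `n` smallest-p genes of the subject-specificity per-gene
#' ranking; all other tested genes form the background. Ties at the n-th
#' p-value are included (with a warning), so slightly more than `n` genes
#' per axis may enter.
#'
#' @param diurnal A `diurnal_result`.
#' @param subject A `specificity_result` (subject axis).
#' @param n Genes per axis (default 250).
#' @return List with `top` and `background` character vectors.
#' @export
select_top_genes <- function(diurnal, subject, n = 250) {
  take <- function(pg) {
    pg <- pg[!is.na(pg$p), , drop = FALSE]
    if (nrow(pg) <= n) {
      warning("fewer than n tested genes; using all")
      return(pg$gene)
    }
    cutoff <- sort(pg$p, partial = n)[n]
    sel <- pg$gene[pg$p <= cutoff]
    if (length(sel) > n)
      warning("ties at the n-th p-value; top set extended to ",
              length(sel), " genes")
    sel
  }
  top <- union(take(diurnal$per_gene), take(subject$per_gene))
  universe <- union(diurnal$per_gene$gene, subject$per_gene$gene)
  list(top = top, background = setdiff(universe, top))
}

#' Weighted pathway and category enrichment (two-proportion z-test)
#'
#' For every pathway, compares the weighted proportion of its genes among
#' the top gene set against the background using the two-proportion z-test
#' on weighted counts: weighted counts enter both the proportions and the
#' effective sample sizes. Categories are tested identically on weighted
#' counts pooled over member pathways.
#'
#' @param db A [load_gmt()] database.
#' @param top,background Character vectors from [select_top_genes()].
#' @param weights Named weights from [gene_weights()]; genes without a
#'   weight (in no pathway) are excluded from the test universe.
#' @return Object of class `enrichment_result`: `pathways` (data.frame
#'   `pathway`, `category`, `n_genes`, `z`, `p`, `undefined`) and
#'   `categories` (data.frame `category`, `n_genes`, `z`, `p`).
#' @export
enrich_pathways <- function(db, top, background, weights) {
  top <- intersect(top, names(weights))
  background <- intersect(background, names(weights))
  if (!length(background))
    .cb_stop("empty background after weighting", "capblood_param_error")
  w1 <- sum(weights[top]); w2 <- sum(weights[background])
  one <- function(members) {
    x1 <- sum(weights[intersect(members, top)])
    x2 <- sum(weights[intersect(members, background)])
    zt <- two_prop_z(x1, w1, x2, w2)
    c(z = zt$z, p = zt$p, undefined = as.numeric(zt$undefined))
  }
  pr <- t(vapply(db$pathways, one, numeric(3)))
  pathways <- data.frame(
    pathway = names(db$pathways),
    category = unname(db$categories[names(db$pathways)]),
    n_genes = vapply(db$pathways, function(m)
      length(intersect(m, c(top, background))), integer(1)),
    z = pr[, "z"], p = pr[, "p"], undefined = pr[, "undefined"] > 0,
    stringsAsFactors = FALSE, row.names = NULL)
  cat_members <- lapply(split(names(db$pathways), db$categories),
                        function(ids)
                          unique(unlist(db$pathways[ids], use.names = FALSE)))
  cr <- t(vapply(cat_members, one, numeric(3)))
  categories <- data.frame(
    category = names(cat_members),
    n_genes = vapply(cat_members, function(m)
      length(intersect(m, c(top, background))), integer(1)),
    z = cr[, "z"], p = cr[, "p"],
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(pathways = pathways, categories = categories),
            class = "enrichment_result")
}
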
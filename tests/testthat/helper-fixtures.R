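# Small shared fixtures, all generated in code.

# a tiny simulated study: 2 planted effects of each kind, no debris
tiny_sim <- function(seed = 11, cells_per_sample = 30, ...) {
  generate_dataset(sim_config(
    n_genes = 150, cells_per_sample = cells_per_sample,
    n_diurnal_global = 2, n_diurnal_celltype = 2, n_subject_specific = 2,
    debris = NULL, seed = seed, ...))
}

# pseudobulk tensor (plus annotation/fractions) from a tiny simulation
tiny_tensor <- function(seed = 11, pooled = FALSE, min_cells = 3, ...) {
  sim <- tiny_sim(seed, ...)
  fr <- normalize_fractions(filter_genes_pre(sim$counts))
  ann <- sim$annotation[match(rownames(fr), sim$annotation$barcode), ]
  list(tensor = build_tensor(fr, ann, sim$design, min_cells = min_cells,
                             pooled = pooled),
       fractions = fr, annotation = ann, sim = sim)
}

# hand-built tensor from explicit group table + value matrix
manual_tensor <- function(groups, mu, genes = colnames(mu)) {
  structure(list(mu = mu, groups = groups, genes = genes, min_cells = 1),
            class = "pseudobulk_tensor")
}

# textbook pooled-variance two-sample t-test (independent oracle)
oracle_t_pooled <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# textbook one-way ANOVA from group sums of squares (independent oracle)
oracle_anova <- function(groups) {
  all <- unlist(groups)
  k <- length(groups); N <- length(all)
  ssb <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - mean(all))^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, p = pf(F, k - 1, N - k, lower.tail = FALSE))
}

# textbook two-proportion z-test on counts (independent oracle)
oracle_two_prop_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2; pp <- (x1 + x2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# cluster annotation via exported scoring, for small hand examples
annotate_clusters_for_test <- function(cm, panel) {
  sc <- score_cluster_annotation(cm, panel)
  apply(sc, 1, function(s) {
    top <- which(s == max(s, na.rm = TRUE))
    if (length(top) > 1) warning("tied annotation scores")
    names(panel)[top[1]]
  })
}

# exhaustive-search BH oracle: largest k with p_(k) <= k/m * alpha
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) / m * alpha)
  reject <- rep(FALSE, m)
  if (length(ks)) reject[o[seq_len(max(ks))]] <- TRUE
  reject
}
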
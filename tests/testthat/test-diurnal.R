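mk_groups <- function(subject, cell_type, period) {
  data.frame(subject = subject, cell_type = cell_type,
             sample = paste0("D", seq_along(period), "_", period),
             day = seq_along(period), period = period, n_cells = 10,
             stringsAsFactors = FALSE)
}

test_that("renormalization subtracts the equally weighted AM/PM mean", {
  # AM means {2, 4}, PM means {6}: offset (3 + 6)/2 = 4.5
  g <- mk_groups("S1", "T", c("AM", "AM", "PM"))
  mu <- matrix(c(2, 4, 6), ncol = 1, dimnames = list(NULL, "g1"))
  rn <- renormalize_eq1(manual_tensor(g, mu))
  expect_equal(unname(rn$mu[, 1]), c(-2.5, -0.5, 1.5))
  # constant series renormalizes to exactly zero
  mu2 <- matrix(5, 3, 1, dimnames = list(NULL, "g1"))
  expect_true(all(renormalize_eq1(manual_tensor(g, mu2))$mu == 0))
})

test_that("renormalized values satisfy the zero-mean identity exactly", {
  tt <- tiny_tensor(seed = 31)
  rn <- suppressWarnings(renormalize_eq1(tt$tensor))
  g <- rn$groups
  for (sc in split(seq_len(nrow(g)), list(g$subject, g$cell_type),
                   drop = TRUE)) {
    am <- sc[g$period[sc] == "AM"]; pm <- sc[g$period[sc] == "PM"]
    resid <- colMeans(rn$mu[am, , drop = FALSE]) / 2 +
      colMeans(rn$mu[pm, , drop = FALSE]) / 2
    expect_lt(max(abs(resid)), 1e-12)
  }
})

test_that("subjects lacking a session class are dropped with a warning", {
  g <- rbind(mk_groups("S1", "T", c("AM", "AM")),
             mk_groups("S2", "T", c("AM", "PM")))
  mu <- matrix(rnorm(4), 4, 1, dimnames = list(NULL, "g1"))
  expect_warning(rn <- renormalize_eq1(manual_tensor(g, mu)),
                 "without both AM and PM")
  expect_equal(unique(rn$groups$subject), "S2")
})

test_that("the AM/PM test matches a textbook pooled t-test and handles ties", {
  am <- c(-1, -2, -1.5, -1.2); pm <- c(1, 2, 1.5, 1.2)
  g <- rbind(mk_groups("S1", "T", rep("AM", 4)),
             mk_groups("S1", "T", rep("PM", 4)))
  g$sample <- paste0(g$sample, seq_len(8))  # unique sample keys
  mu <- matrix(c(am, pm), ncol = 1, dimnames = list(NULL, "g1"))
  res <- diurnal_test(manual_tensor(g, mu))
  orc <- oracle_t_pooled(am, pm)
  expect_equal(res$tests$t, orc$t, tolerance = 1e-12)
  expect_equal(res$tests$p, orc$p, tolerance = 1e-12)
  expect_equal(res$tests$z, sign(mean(am) - mean(pm)) *
                 qnorm(orc$p / 2, lower.tail = FALSE), tolerance = 1e-10)
  # identical AM and PM values: t = 0, p = 1
  mu2 <- matrix(rep(c(1, 2, 3, 4), 2), ncol = 1,
                dimnames = list(NULL, "g1"))
  res2 <- diurnal_test(manual_tensor(g, mu2))
  expect_equal(res2$tests$t, 0)
  expect_equal(res2$tests$p, 1)
  # zero variance with unequal means: flagged degenerate
  mu3 <- matrix(c(rep(1, 4), rep(2, 4)), ncol = 1,
                dimnames = list(NULL, "g1"))
  res3 <- diurnal_test(manual_tensor(g, mu3))
  expect_true(res3$tests$degenerate)
  expect_equal(res3$tests$t, -Inf)
})

test_that("statistics are invariant to rescaling all means", {
  tt <- tiny_tensor(seed = 32)
  rn <- suppressWarnings(renormalize_eq1(tt$tensor))
  res1 <- suppressWarnings(diurnal_test(rn))
  rn2 <- rn; rn2$mu <- rn2$mu * 1e4
  res2 <- suppressWarnings(diurnal_test(rn2))
  expect_equal(res1$tests$t, res2$tests$t, tolerance = 1e-9)
  expect_equal(res1$tests$p, res2$tests$p, tolerance = 1e-9)
  sp1 <- suppressWarnings(subject_specificity_test(tt$tensor))
  tt2 <- tt$tensor; tt2$mu <- tt2$mu * 1e4
  sp2 <- suppressWarnings(subject_specificity_test(tt2))
  expect_equal(sp1$tests$F, sp2$tests$F, tolerance = 1e-9)
})

test_that("per-gene summary picks the minimum-p cell type jointly corrected", {
  tt <- tiny_tensor(seed = 33)
  res <- suppressWarnings(diurnal_test(renormalize_eq1(tt$tensor)))
  expect_true(all(res$tests$q >= res$tests$p, na.rm = TRUE))
  expect_equal(res$tests$significant, res$tests$q <= res$fdr)
  one <- res$per_gene[1, ]
  mine <- res$tests[res$tests$gene == one$gene, ]
  expect_equal(one$p, min(mine$p))
  expect_equal(one$cell_type, mine$cell_type[which.min(mine$p)])
})

test_that("pooled test on a single-type dataset equals the per-type test", {
  tt <- tiny_tensor(seed = 34, min_cells = 1)
  ann1 <- tt$annotation; ann1$cell_type <- "only"
  t1 <- build_tensor(tt$fractions, ann1, tt$sim$design, min_cells = 1)
  tp <- build_tensor(tt$fractions, ann1, tt$sim$design, min_cells = 1,
                     pooled = TRUE)
  r1 <- diurnal_test(renormalize_eq1(t1))
  rp <- population_level_test(renormalize_eq1(tp))
  expect_equal(r1$tests$t, rp$tests$t)
  expect_equal(r1$tests$q, rp$tests$q)
})

test_that("diurnal classification is exclusive and complete", {
  tt <- tiny_tensor(seed = 35)
  rn <- suppressWarnings(renormalize_eq1(tt$tensor))
  pooled <- build_tensor(tt$fractions, tt$annotation, tt$sim$design,
                         pooled = TRUE)
  res_ct <- suppressWarnings(diurnal_test(rn))
  res_pop <- population_level_test(renormalize_eq1(pooled))
  cls <- classify_diurnal(res_ct, res_pop)
  expect_setequal(cls$gene, union(res_ct$per_gene$gene,
                                  res_pop$per_gene$gene))
  expect_true(all(cls$class %in% c("both", "celltype_specific",
                                   "population_only_abundance_suspect",
                                   "none")))
  # forcing significance off yields all-none
  res_ct0 <- res_ct; res_ct0$tests$significant <- FALSE
  res_pop0 <- res_pop; res_pop0$per_gene$significant <- FALSE
  expect_true(all(classify_diurnal(res_ct0, res_pop0)$class == "none"))
})

test_that("abundance shift test is symmetric under direction reversal", {
  sim <- tiny_sim(seed = 36)
  ab_pm <- abundance_shift_test(sim$annotation, "B cells", "PM_greater")
  ab_am <- abundance_shift_test(sim$annotation, "B cells", "AM_greater")
  expect_equal(ab_pm$p + ab_am$p, 1, tolerance = 1e-12)
  # identical AM/PM fraction sets: one-sided p = 0.5
  ann <- data.frame(
    barcode = paste0("b", 1:8),
    subject = rep(c("S1", "S2"), each = 4),
    sample = rep(c("D1_AM", "D1_PM"), 4),
    session = rep(c("AM", "PM"), 4),
    cell_type = rep(c("B cells", "T cells"), each = 2, times = 2),
    is_debris = FALSE)
  ab <- abundance_shift_test(ann, "B cells")
  expect_equal(ab$p, 0.5)
})

test_that("abundance reports the largest expressing-cell percentage", {
  counts <- Matrix::Matrix(rbind(c(1, 0), c(1, 0), c(0, 0), c(1, 1)),
                           sparse = TRUE)
  dimnames(counts) <- list(paste0("b", 1:4), c("g1", "g2"))
  types <- c("A", "A", "B", "B")
  ab <- expression_abundance(counts, types)
  expect_equal(unname(ab["g1"]), 100)  # 100% of A cells
  expect_equal(unname(ab["g2"]), 50)   # 50% of B cells
})
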
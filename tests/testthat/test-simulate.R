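test_that("identical config and seed give byte-identical datasets", {
  a <- tiny_sim(seed = 5)
  b <- tiny_sim(seed = 5)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
})

test_that("null configuration plants nothing", {
  sim <- generate_dataset(sim_config(
    n_genes = 60, cells_per_sample = 20, n_diurnal_global = 0,
    n_diurnal_celltype = 0, n_subject_specific = 0,
    abundance_shift = NULL, debris = NULL, seed = 2))
  expect_equal(nrow(sim$truth$diurnal_genes), 0)
  expect_equal(nrow(sim$truth$subject_genes), 0)
  expect_length(sim$truth$debris_barcodes, 0)
})

test_that("invalid configurations are rejected", {
  bad_types <- default_cell_types()
  bad_types[[1]]$baseline_fraction <- 0.5
  expect_error(sim_config(cell_types = bad_types), "sum to 1")
  dup <- default_cell_types()
  dup[[2]]$marker_genes <- dup[[1]]$marker_genes
  fr <- vapply(dup, `[[`, numeric(1), "baseline_fraction")
  expect_error(sim_config(cell_types = dup), "disjoint")
  expect_error(sim_config(n_genes = 10), "too small")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(
    sim_config(abundance_shift = list(cell_type = "Platelets",
                                      am_fraction = .1, pm_fraction = .2)),
    "not in cell_types")
})

test_that("registered genes and barcodes all exist in the emitted matrix", {
  sim <- tiny_sim(seed = 9)
  expect_true(all(sim$truth$diurnal_genes$gene %in% colnames(sim$counts)))
  expect_true(all(sim$truth$subject_genes$gene %in% colnames(sim$counts)))
  expect_true(all(names(sim$truth$celltype_of_barcode) %in%
                  rownames(sim$counts)))
  expect_true(all(sim$counts@x >= 0))
  expect_true(all(sim$counts@x == round(sim$counts@x)))
})

test_that("empirical composition converges to configured fractions", {
  cfg <- sim_config(n_genes = 60, cells_per_sample = 400,
                    n_diurnal_global = 0, n_diurnal_celltype = 0,
                    n_subject_specific = 0, debris = NULL, seed = 31)
  sim <- generate_dataset(cfg)
  emp <- prop.table(table(sim$annotation$cell_type))
  conf <- vapply(cfg$cell_types, `[[`, numeric(1), "baseline_fraction")
  names(conf) <- vapply(cfg$cell_types, `[[`, character(1), "name")
  n <- nrow(sim$annotation)
  for (ct in names(conf)) {
    se <- sqrt(conf[ct] * (1 - conf[ct]) / n) +
      sqrt(conf[ct] * (1 - conf[ct]) / 1000) / sqrt(24)  # dirichlet part
    expect_lt(abs(emp[ct] - conf[ct]), 3 * se + 0.01)
  }
})

test_that("configured AM/PM abundance shift appears in sample fractions", {
  sim <- generate_dataset(scenario_confound(seed = 4))
  fr <- sample_celltype_fractions(sim$annotation)
  diff <- mean(fr[fr$period == "PM", "B cells"]) -
    mean(fr[fr$period == "AM", "B cells"])
  expect_gt(diff, 0.03)   # configured 0.06 within sampling error
  expect_lt(diff, 0.09)
})

test_that("debris UMI totals sit below cell totals", {
  sim <- generate_dataset(scenario_debris(seed = 3))
  totals <- Matrix::rowSums(sim$counts)
  deb <- sim$annotation$is_debris
  expect_lt(median(totals[deb]), median(totals[!deb]))
  # stochastic dominance below: debris quartiles under cell quartiles
  expect_true(all(quantile(totals[deb], c(.25, .5, .75)) <
                  quantile(totals[!deb], c(.25, .5, .75))))
})

test_that("planted diurnal genes shift pseudobulk in the configured direction", {
  tt <- tiny_tensor(seed = 21, cells_per_sample = 150)
  rn <- renormalize_eq1(tt$tensor)
  truth <- tt$sim$truth$diurnal_genes
  g <- rn$groups
  ok <- 0; tot <- 0
  for (i in seq_len(nrow(truth))) {
    cts <- if (truth$scope[i] == "ALL") unique(g$cell_type)
           else truth$scope[i]
    for (ct in cts) {
      rows <- which(g$cell_type == ct)
      d <- mean(rn$mu[rows[g$period[rows] == "PM"], truth$gene[i]]) -
        mean(rn$mu[rows[g$period[rows] == "AM"], truth$gene[i]])
      tot <- tot + 1
      ok <- ok + (sign(d) == truth$direction[i])
    }
  }
  expect_gte(ok / tot, 0.9)
})

test_that("missing samples are absent from the emitted data", {
  miss <- data.frame(subject = "S1", day = 2, session = "PM")
  sim <- generate_dataset(sim_config(
    n_genes = 60, cells_per_sample = 20, n_diurnal_global = 0,
    n_diurnal_celltype = 0, n_subject_specific = 0, debris = NULL,
    missing_samples = miss, seed = 8))
  ann <- sim$annotation
  expect_equal(sum(ann$subject == "S1" & ann$sample == "D2_PM"), 0)
  expect_equal(unname(sim$design$n_sessions["S1"]), 5)
})
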
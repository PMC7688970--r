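toy_gmt <- system.file("extdata", "toy_pathways.gmt", package = "capblood")
toy_cats <- system.file("extdata", "toy_pathway_categories.tsv",
                        package = "capblood")

test_that("GMT loading joins categories and enforces integrity", {
  db <- load_gmt(toy_gmt, toy_cats)
  expect_length(db$pathways, 12)
  expect_equal(unname(db$categories["PW_LEUKEMIA"]), "Immune Diseases")
  expect_equal(unname(db$categories["PW_VIRAL_INFECTION"]),
               "Infectious Diseases")
  # missing sidecar rows fall back to Other with a warning
  sc <- read.delim(toy_cats)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(sc[-1, ], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(db2 <- load_gmt(toy_gmt, f), "Other")
  expect_equal(unname(db2$categories["PW_TCR_SIGNALING"]), "Other")
  # duplicate pathway ids are rejected
  g <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("PW_A\tdesc\tg1\tg2", "PW_A\tdesc\tg3"), g)
  expect_error(load_gmt(g), "duplicate")
})

test_that("gene weights are reciprocal pathway membership", {
  db <- load_gmt(toy_gmt, toy_cats)
  w <- gene_weights(db)
  # CD4 appears in exactly one toy pathway, G00010 in two, G00095 in three
  expect_equal(unname(w["CD4"]), 1)
  expect_equal(unname(w["G00010"]), 1 / 2)
  expect_equal(unname(w["G00095"]), 1 / 3)
  expect_false("NOT_A_GENE" %in% names(w))
  w2 <- gene_weights(db, genes_in_data = c("CD4", "G00010"))
  expect_setequal(names(w2), c("CD4", "G00010"))
  # conservation: membership count x weight = 1 for every gene
  counts <- table(unlist(db$pathways))
  expect_true(all(abs(w[names(counts)] * as.numeric(counts) - 1) < 1e-12))
})

test_that("top-gene selection takes the per-axis union and keeps ties", {
  mk_res <- function(genes, p) {
    structure(list(per_gene = data.frame(gene = genes, p = p)),
              class = "diurnal_result")
  }
  d <- mk_res(paste0("g", 1:10), seq(0.01, 0.1, by = 0.01))
  s <- mk_res(paste0("g", 1:10), rev(seq(0.01, 0.1, by = 0.01)))
  sel <- select_top_genes(d, s, n = 3)
  expect_setequal(sel$top, c("g1", "g2", "g3", "g8", "g9", "g10"))
  expect_setequal(sel$background, paste0("g", 4:7))
  # ties at the n-th p extend the set with a warning
  d2 <- mk_res(paste0("g", 1:6), c(0.01, 0.02, 0.02, 0.02, 0.5, 0.6))
  expect_warning(                       # one tie warning per axis
    expect_warning(sel2 <- select_top_genes(d2, d2, n = 2), "ties"),
    "ties")
  expect_setequal(sel2$top, c("g1", "g2", "g3", "g4"))
  # n exceeding the universe uses everything and the test step then fails
  expect_warning(
    expect_warning(sel3 <- select_top_genes(d, s, n = 50), "fewer than n"),
    "fewer than n")
  expect_length(sel3$background, 0)
  db <- load_gmt(toy_gmt, toy_cats)
  w <- gene_weights(db)
  expect_error(enrich_pathways(db, sel3$top, sel3$background, w),
               "empty background")
})

test_that("unit weights reduce the weighted test to the textbook z-test", {
  db <- list(pathways = list(P1 = paste0("g", 1:20)),
             categories = c(P1 = "Cat"))
  class(db) <- "pathway_db"
  top <- paste0("g", 1:30)                 # 8 of P1's genes in the top set
  background <- paste0("g", 31:130)
  db$pathways$P1 <- c(paste0("g", 1:8), paste0("g", 31:42))
  w <- setNames(rep(1, 130), paste0("g", 1:130))
  res <- enrich_pathways(db, top, background, w)
  orc <- oracle_two_prop_z(8, 30, 12, 100)
  expect_equal(res$pathways$z, orc$z, tolerance = 1e-12)
  expect_equal(res$pathways$p, orc$p, tolerance = 1e-12)
  # antisymmetry under swapping top and background
  res_sw <- enrich_pathways(db, background, top, w)
  expect_equal(res_sw$pathways$z, -res$pathways$z, tolerance = 1e-12)
})

test_that("a category concentrating the top genes has the maximal z", {
  db <- load_gmt(toy_gmt, toy_cats)
  w <- gene_weights(db)
  # put the immune pathways' member genes in the top set
  imm <- unique(unlist(
    db$pathways[names(db$categories)[db$categories == "Immune System"]]))
  universe <- names(w)
  res <- enrich_pathways(db, intersect(imm, universe),
                         setdiff(universe, imm), w)
  best <- res$categories$category[which.max(res$categories$z)]
  expect_equal(best, "Immune System")
  # identical proportions give z = 0
  res0 <- enrich_pathways(db, universe, universe, w)
  expect_true(all(abs(res0$pathways$z) < 1e-12))
})
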
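#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end pipeline. Input is
#' either a directory of 10x-style files plus a metadata TSV
#' (`input_dir`), or a [sim_config()] (`simulate`) to generate data on the
#' fly.
#'
#' @param input_dir Directory with `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`, `metadata.tsv` (ignored when `simulate` is given).
#' @param simulate Optional [sim_config()].
#' @param output_dir Directory for result TSVs and the run summary.
#' @param expected_cells Expected cell count for debris removal; defaults
#'   to 1.25x the study target when simulating.
#' @param debris_enabled Run the debris-removal stage.
#' @param min_max_count,min_type_fraction Gene filter parameters.
#' @param embed_d,k_min,k_max Typing parameters.
#' @param marker_panel Named list for cluster annotation.
#' @param min_cells Pseudobulk masking floor.
#' @param fdr FDR level for all tests.
#' @param gmt,gmt_categories Optional pathway GMT and category sidecar
#'   paths; enrichment is skipped when `gmt` is `NULL`.
#' @param top_n Genes per axis for the enrichment top set.
#' @param seed Integer seed for the run.
#' @return List of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, simulate = NULL,
                       output_dir = tempfile("capblood_run"),
                       expected_cells = NULL, debris_enabled = TRUE,
                       min_max_count = 3, min_type_fraction = 0.10,
                       embed_d = 10, k_min = 13, k_max = 15,
                       marker_panel = default_marker_panel(),
                       min_cells = 3, fdr = 0.05,
                       gmt = NULL, gmt_categories = NULL, top_n = 250,
                       seed = 1L) {
  if (is.null(input_dir) && is.null(simulate))
    .cb_stop("either input_dir or simulate must be given",
             "capblood_config_error")
  if (fdr <= 0 || fdr >= 1)
    .cb_stop("fdr must lie in (0, 1)", "capblood_config_error")
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; a `simulate` block
#' mirrors [sim_config()] fields (with `abundance_shift` as a mapping of
#' `cell_type`, `am_fraction`, `pm_fraction`).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(run_config, y)
}

.write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, debris removal, the pre-typing gene filter,
#' embedding and cell typing, the post-typing gene filter, pseudobulk
#' tensor construction, the diurnal per-type and population-level tests
#' with abundance-shift disambiguation, the subject- and
#' cell-type-specificity ANOVAs, and (when a GMT is configured) weighted
#' pathway enrichment. All intermediates are persisted as TSV under the
#' output directory; runs are deterministic given the seed.
#'
#' @param config A [run_config()].
#' @return A `run_summary` list: per-stage parameter echo and counts
#'   (barcodes kept, genes kept, cells per type, significant genes per test
#'   and class), also written to `summary.json`.
#' @export
run_pipeline <- function(config) {
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  set.seed(config$seed)
  summary <- list(seed = config$seed,
                  version = as.character(utils::packageVersion("capblood")),
                  stages = list())
  log_stage <- function(name, ...) {
    info <- list(...)
    summary$stages[[name]] <<- info
    message(sprintf("[%s] %s", name,
                    paste(names(info), unlist(lapply(info, paste,
                          collapse = ",")), sep = "=", collapse = " ")))
  }

  # -- ingest or simulate ----------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- generate_dataset(config$simulate)
    counts <- sim$counts; annotation <- sim$annotation
    design <- sim$design; truth <- sim$truth
  } else {
    counts <- read_tenx_dir(config$input_dir)
    md <- read_metadata(file.path(config$input_dir, "metadata.tsv"), counts)
    annotation <- md$annotation; design <- md$design; truth <- NULL
  }
  log_stage("ingest", barcodes = nrow(counts), genes = ncol(counts))

  # -- debris removal ---------------------------------------------------
  if (config$debris_enabled) {
    expected <- config$expected_cells
    if (is.null(expected))
      expected <- round(1.25 * sum(annotation$subject != "unassigned"))
    dc <- remove_debris(counts, expected_cells = expected)
    keep <- names(dc$call)[dc$call == "keep"]
    .write_tsv(data.frame(barcode = names(dc$call), call = dc$call),
               file.path(out, "debris_calls.tsv"))
    .write_tsv(data.frame(cluster = rownames(dc$traces$normalized),
                          class = dc$cluster_class[
                            rownames(dc$traces$normalized)],
                          dc$traces$normalized, check.names = FALSE),
               file.path(out, "dropoff_traces.tsv"))
    counts <- counts[keep, , drop = FALSE]
    annotation <- annotation[match(keep, annotation$barcode), , drop = FALSE]
    log_stage("debris", threshold = dc$threshold, k = dc$k,
              kept = length(keep))
  } else {
    log_stage("debris", skipped = TRUE, kept = nrow(counts))
  }

  # -- pre-typing gene filter + normalization --------------------------
  counts <- filter_genes_pre(counts, config$min_max_count)
  log_stage("filter_pre", min_max_count = config$min_max_count,
            genes = ncol(counts))
  fractions <- normalize_fractions(counts)
  counts <- counts[rownames(fractions), , drop = FALSE]
  annotation <- annotation[match(rownames(fractions), annotation$barcode), ,
                           drop = FALSE]

  # -- embedding + cell typing -----------------------------------------
  emb <- embed_cells(fractions, d = config$embed_d)
  typing <- cluster_cells(emb, fractions, config$marker_panel,
                          config$k_min, config$k_max)
  annotation$cell_type <- unname(typing$cell_type[annotation$barcode])
  .write_tsv(annotation, file.path(out, "cell_annotation.tsv"))
  log_stage("celltype", k = typing$k,
            types = length(unique(stats::na.omit(annotation$cell_type))))

  # -- post-typing gene filter -----------------------------------------
  counts <- filter_genes_post(counts, annotation$cell_type,
                              config$min_type_fraction)
  fractions <- fractions[, colnames(counts), drop = FALSE]
  log_stage("filter_post", min_type_fraction = config$min_type_fraction,
            genes = ncol(counts))

  # -- pseudobulk tensors ----------------------------------------------
  tensor <- build_tensor(fractions, annotation, design, config$min_cells)
  tensor_pooled <- build_tensor(fractions, annotation, design,
                                config$min_cells, pooled = TRUE)
  .write_tsv(as.data.frame(tensor), file.path(out, "pseudobulk.tsv"))
  log_stage("pseudobulk", groups = nrow(tensor$groups),
            masked = sum(is.na(tensor$mu[, 1])))

  # -- diurnal detection ------------------------------------------------
  abund <- expression_abundance(counts, annotation$cell_type)
  diurnal_ct <- diurnal_test(renormalize_eq1(tensor), config$fdr,
                             abundance = abund)
  diurnal_pop <- population_level_test(renormalize_eq1(tensor_pooled),
                                       config$fdr, abundance = abund)
  classes <- classify_diurnal(diurnal_ct, diurnal_pop)
  .write_tsv(diurnal_ct$tests, file.path(out, "diurnal_celltype.tsv"))
  .write_tsv(diurnal_pop$tests, file.path(out, "diurnal_population.tsv"))
  .write_tsv(classes, file.path(out, "diurnal_classes.tsv"))
  log_stage("diurnal",
            significant_celltype = sum(diurnal_ct$tests$significant),
            significant_population = sum(diurnal_pop$tests$significant),
            classes = paste(names(table(classes$class)),
                            table(classes$class), sep = ":"))

  # -- abundance shifts per cell type ----------------------------------
  shift <- do.call(rbind, lapply(
    sort(unique(stats::na.omit(annotation$cell_type))), function(ct) {
      s <- abundance_shift_test(annotation, ct, "PM_greater")
      data.frame(cell_type = ct, t = s$t, p = s$p, mean_am = s$mean_am,
                 mean_pm = s$mean_pm, stringsAsFactors = FALSE)
    }))
  .write_tsv(shift, file.path(out, "abundance_shift.tsv"))

  # -- specificity ANOVAs ----------------------------------------------
  subj <- subject_specificity_test(tensor, config$fdr)
  ctsp <- celltype_specificity_test(tensor, config$fdr)
  .write_tsv(subj$tests, file.path(out, "subject_specificity.tsv"))
  .write_tsv(ctsp$tests, file.path(out, "celltype_specificity.tsv"))
  log_stage("specificity",
            subject_specific = sum(subj$per_gene$significant, na.rm = TRUE),
            celltype_specific = sum(ctsp$per_gene$significant,
                                    na.rm = TRUE))

  # -- pathway enrichment ----------------------------------------------
  if (!is.null(config$gmt)) {
    db <- load_gmt(config$gmt, config$gmt_categories)
    w <- gene_weights(db, tensor$genes)
    sel <- select_top_genes(diurnal_ct, subj, config$top_n)
    enr <- enrich_pathways(db, sel$top, sel$background, w)
    .write_tsv(enr$pathways, file.path(out, "pathway_enrichment.tsv"))
    .write_tsv(enr$categories, file.path(out, "category_enrichment.tsv"))
    log_stage("pathways", n_pathways = nrow(enr$pathways),
              top_set = length(sel$top))
  }

  summary$counts <- list(
    barcodes_kept = nrow(counts), genes_kept = ncol(counts),
    cells_per_type = as.list(table(annotation$cell_type)),
    diurnal_significant_genes =
      sum(diurnal_ct$per_gene$significant, na.rm = TRUE),
    population_significant_genes =
      sum(diurnal_pop$per_gene$significant, na.rm = TRUE),
    subject_specific_genes =
      sum(subj$per_gene$significant, na.rm = TRUE),
    class_counts = as.list(table(classes$class)))
  if (!is.null(truth)) summary$truth_available <- TRUE
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  structure(summary, class = "run_summary")
}
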
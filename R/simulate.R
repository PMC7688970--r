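#' Cell type specification for the synthetic generator
#'
#' @param name Cell type label.
#' @param baseline_fraction Expected fraction of cells of this type in a
#'   sample (before any AM/PM abundance shift).
#' @param marker_genes Character vector of marker gene symbols, elevated in
#'   this type only. Marker lists must be disjoint across types.
#' @param marker_log2fc log2 fold elevation of the marker genes in this type
#'   relative to their baseline rate in other types.
#' @return A list of class `cell_type_spec`.
#' @export
cell_type_spec <- function(name, baseline_fraction, marker_genes,
                           marker_log2fc = 4) {
  stopifnot(is.character(name), length(name) == 1,
            baseline_fraction > 0, baseline_fraction < 1,
            length(marker_genes) >= 1, marker_log2fc >= 0)
  structure(list(name = name, baseline_fraction = baseline_fraction,
                 marker_genes = as.character(marker_genes),
                 marker_log2fc = marker_log2fc),
            class = "cell_type_spec")
}

#' Default six-type PBMC panel for simulation and annotation
#'
#' The major peripheral-blood mononuclear cell types (CD4+/CD8+ T cells,
#' NK cells, CD14+/CD16+ monocytes, B cells) with canonical, mutually
#' disjoint marker genes and realistic baseline proportions.
#'
#' @return A list of [cell_type_spec()] objects.
#' @export
default_cell_types <- function() {
  list(
    cell_type_spec("CD4 T cells",     0.32, c("CD4", "IL7R", "CCR7")),
    cell_type_spec("CD8 T cells",     0.20, c("CD8A", "CD8B", "GZMK")),
    cell_type_spec("CD14+ Monocytes", 0.18, c("CD14", "LYZ", "S100A8")),
    cell_type_spec("NK cells",        0.15, c("NKG7", "GNLY", "KLRD1")),
    cell_type_spec("B cells",         0.10, c("MS4A1", "CD79A", "CD79B")),
    cell_type_spec("CD16+ Monocytes", 0.05, c("FCGR3A", "MS4A7", "LST1"))
  )
}

#' Debris droplet specification
#'
#' @param n_debris_barcodes Number of debris barcodes emitted per session.
#' @param umi_scale_factor Ratio of debris to cell median library size,
#'   in (0, 1).
#' @param ambient_mixing Fraction of the debris expression profile drawn
#'   from a uniform profile rather than the session ambient profile.
#' @return A list of class `debris_spec`.
#' @export
debris_spec <- function(n_debris_barcodes = 200, umi_scale_factor = 0.05,
                        ambient_mixing = 0.3) {
  stopifnot(n_debris_barcodes >= 0,
            umi_scale_factor > 0, umi_scale_factor < 1,
            ambient_mixing >= 0, ambient_mixing <= 1)
  structure(list(n_debris_barcodes = n_debris_barcodes,
                 umi_scale_factor = umi_scale_factor,
                 ambient_mixing = ambient_mixing),
            class = "debris_spec")
}

#' Configuration of the synthetic capillary-blood study
#'
#' Parameterizes a multi-subject, multi-day AM/PM single-cell study with
#' planted diurnal genes (global and cell-type-restricted), planted
#' subject-specific genes, an optional AM-to-PM cell-type abundance shift,
#' and debris droplets. Defaults mirror the study design the package
#' targets: 4 subjects sampled each morning and afternoon over 3
#' consecutive days.
#'
#' Counts are gamma-Poisson (negative binomial) around
#' `library size x relative gene rate`, with marker, diurnal, and
#' subject effects applied multiplicatively on the rate scale, a per-(gene,
#' subject-session) log-normal sample-level noise factor shared across cell
#' types, and per-sample cell-type composition drawn from a Dirichlet
#' distribution around the (possibly shifted) baseline fractions.
#'
#' @param n_subjects,n_days Study dimensions (default 4 subjects, 3 days;
#'   every day has an AM and a PM session).
#' @param n_genes Total number of genes, including markers.
#' @param cell_types List of [cell_type_spec()]; baseline fractions must sum
#'   to 1 and marker lists must be disjoint.
#' @param cells_per_sample Cells recovered per subject per session.
#' @param library_size_log_mean,library_size_log_sd Log-normal parameters of
#'   per-cell total UMI.
#' @param nb_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param n_diurnal_global,n_diurnal_celltype,n_subject_specific Numbers of
#'   planted effect genes.
#' @param diurnal_log2fc,subject_log2fc Planted effect sizes (log2 fold
#'   change of the expression rate).
#' @param diurnal_host Cell type carrying the cell-type-restricted diurnal
#'   genes.
#' @param abundance_shift `NULL`, or a list with `cell_type`, `am_fraction`,
#'   `pm_fraction` describing a session-period-dependent composition shift;
#'   the remaining types are rescaled so fractions sum to 1.
#' @param composition_precision Dirichlet precision of per-sample
#'   composition around its target.
#' @param sample_noise_sd Standard deviation (natural-log scale) of the
#'   per-(gene, subject-session) expression noise factor.
#' @param debris A [debris_spec()], or `NULL` for no debris.
#' @param missing_samples Optional data.frame (`subject`, `day`, `session`)
#'   of subject-sessions to drop, emulating failed collections.
#' @param seed Integer seed; identical configs with identical seeds produce
#'   identical datasets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 4,
                       n_days = 3,
                       n_genes = 2000,
                       cell_types = default_cell_types(),
                       cells_per_sample = 1000,
                       library_size_log_mean = log(2000),
                       library_size_log_sd = 0.35,
                       nb_dispersion = 2,
                       n_diurnal_global = 20,
                       n_diurnal_celltype = 20,
                       n_subject_specific = 20,
                       diurnal_log2fc = 2,
                       subject_log2fc = 2,
                       diurnal_host = "B cells",
                       abundance_shift = NULL,
                       composition_precision = 1000,
                       sample_noise_sd = 0.2,
                       debris = debris_spec(),
                       missing_samples = NULL,
                       seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_days = n_days, n_genes = n_genes,
              cell_types = cell_types, cells_per_sample = cells_per_sample,
              library_size_log_mean = library_size_log_mean,
              library_size_log_sd = library_size_log_sd,
              nb_dispersion = nb_dispersion,
              n_diurnal_global = n_diurnal_global,
              n_diurnal_celltype = n_diurnal_celltype,
              n_subject_specific = n_subject_specific,
              diurnal_log2fc = diurnal_log2fc,
              subject_log2fc = subject_log2fc,
              diurnal_host = diurnal_host,
              abundance_shift = abundance_shift,
              composition_precision = composition_precision,
              sample_noise_sd = sample_noise_sd,
              debris = debris, missing_samples = missing_samples,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_subjects < 1 || n_days < 1 || n_genes < 1 || cells_per_sample < 1)
      .cb_stop("all counts must be positive", "capblood_config_error")
    if (nb_dispersion <= 0)
      .cb_stop("nb_dispersion must be > 0", "capblood_config_error")
    fr <- vapply(cell_types, `[[`, numeric(1), "baseline_fraction")
    if (abs(sum(fr) - 1) > 1e-8)
      .cb_stop("cell type baseline fractions must sum to 1",
               "capblood_config_error")
    markers <- unlist(lapply(cell_types, `[[`, "marker_genes"))
    if (anyDuplicated(markers))
      .cb_stop("marker gene lists must be disjoint across cell types",
               "capblood_config_error")
    if (length(markers) + n_diurnal_global + n_diurnal_celltype +
        n_subject_specific > n_genes)
      .cb_stop("n_genes too small for markers plus planted effect genes",
               "capblood_config_error")
    if (!is.null(abundance_shift)) {
      nm <- vapply(cell_types, `[[`, character(1), "name")
      if (!abundance_shift$cell_type %in% nm)
        .cb_stop("abundance_shift cell type not in cell_types",
                 "capblood_config_error")
      if (any(c(abundance_shift$am_fraction, abundance_shift$pm_fraction)
              <= 0 | c(abundance_shift$am_fraction,
                       abundance_shift$pm_fraction) >= 1))
        .cb_stop("abundance shift fractions must lie in (0,1)",
                 "capblood_config_error")
    }
    if (n_diurnal_celltype > 0 &&
        !diurnal_host %in% vapply(cell_types, `[[`, character(1), "name"))
      .cb_stop("diurnal_host not in cell_types", "capblood_config_error")
  })
  invisible(cfg)
}

# target composition for one session period, shift applied and renormalized
.session_composition <- function(base, type_names, shift, period) {
  comp <- base
  if (!is.null(shift)) {
    i <- match(shift$cell_type, type_names)
    f <- if (period == "PM") shift$pm_fraction else shift$am_fraction
    comp[-i] <- comp[-i] * (1 - f) / sum(comp[-i])
    comp[i] <- f
  }
  comp
}

#' Generate a synthetic capillary-blood single-cell dataset
#'
#' Draws a full multi-subject AM/PM study from a [sim_config()]: one barcode
#' per simulated cell and per debris droplet, a sparse barcodes x genes UMI
#' count matrix, a per-barcode annotation, the sample design, and a
#' ground-truth registry of every planted effect.
#'
#' Debris droplets draw their expression from the session's ambient profile
#' (the library-size-weighted mean of its cell profiles) mixed with a
#' uniform profile, at a library size scaled down by
#' `debris$umi_scale_factor`.
#'
#' @param config A [sim_config()].
#' @return A list of class `capblood_sim` with elements `counts` (sparse
#'   dgCMatrix, barcodes x genes), `features` (data.frame `id`, `symbol`),
#'   `annotation` (data.frame `barcode`, `subject`, `day`, `session`,
#'   `sample`, `cell_type`, `is_debris`), `design` ([sample_design()]),
#'   `truth` (planted-effect registry) and `config`.
#' @examples
#' cfg <- sim_config(n_genes = 120, cells_per_sample = 20,
#'                   n_diurnal_global = 2, n_diurnal_celltype = 2,
#'                   n_subject_specific = 2, debris = NULL, seed = 7)
#' sim <- generate_dataset(cfg)
#' dim(sim$counts)
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  G <- config$n_genes
  types <- config$cell_types
  type_names <- vapply(types, `[[`, character(1), "name")
  Tn <- length(types)
  subjects <- paste0("S", seq_len(config$n_subjects))
  design <- sample_design(subjects, config$n_days, config$missing_samples)
  sessions <- design$sessions

  # gene universe: markers keep their symbols as ids, the rest are G-ids
  markers <- unlist(lapply(types, `[[`, "marker_genes"))
  gene_ids <- c(markers, sprintf("G%05d", seq_len(G - length(markers))))
  features <- data.frame(id = gene_ids, symbol = gene_ids,
                         stringsAsFactors = FALSE)

  # baseline relative expression rates, heavy-tailed; planted genes are
  # drawn from the non-marker pool and lifted to a moderate expression
  # quantile so that effects land on genes the filters retain
  rate <- exp(rnorm(G, 0, 1.5))
  q70_90 <- function(n) exp(stats::runif(n, 1.5 * 0.5244, 1.5 * 1.2816))
  marker_idx <- seq_along(markers)
  rate[marker_idx] <- q70_90(length(markers))

  n_eff <- config$n_diurnal_global + config$n_diurnal_celltype +
    config$n_subject_specific
  pool <- setdiff(seq_len(G), marker_idx)
  eff_idx <- if (n_eff > 0) sample(pool, n_eff) else integer(0)
  rate[eff_idx] <- q70_90(n_eff)
  rate <- rate / sum(rate)

  dg_idx <- eff_idx[seq_len(config$n_diurnal_global)]
  dc_idx <- eff_idx[config$n_diurnal_global + seq_len(config$n_diurnal_celltype)]
  sj_idx <- eff_idx[config$n_diurnal_global + config$n_diurnal_celltype +
                      seq_len(config$n_subject_specific)]

  # multiplicative effect matrices on the rate scale (genes x types)
  M <- matrix(1, G, Tn, dimnames = list(gene_ids, type_names))
  off <- 0
  for (t in seq_len(Tn)) {
    nm <- length(types[[t]]$marker_genes)
    M[off + seq_len(nm), t] <- 2^types[[t]]$marker_log2fc
    off <- off + nm
  }
  D_pm <- matrix(1, G, Tn)
  dir_dg <- sample(c(-1, 1), length(dg_idx), replace = TRUE)
  dir_dc <- sample(c(-1, 1), length(dc_idx), replace = TRUE)
  if (length(dg_idx)) D_pm[dg_idx, ] <- 2^(dir_dg * config$diurnal_log2fc)
  host <- match(config$diurnal_host, type_names)
  if (length(dc_idx)) D_pm[dc_idx, host] <- 2^(dir_dc * config$diurnal_log2fc)

  sj_subject <- sample(subjects, length(sj_idx), replace = TRUE)
  sj_type <- sample(type_names, length(sj_idx), replace = TRUE)
  dir_sj <- sample(c(-1, 1), length(sj_idx), replace = TRUE)
  S_mult <- lapply(subjects, function(s) matrix(1, G, Tn))
  names(S_mult) <- subjects
  for (i in seq_along(sj_idx)) {
    S_mult[[sj_subject[i]]][sj_idx[i], match(sj_type[i], type_names)] <-
      2^(dir_sj[i] * config$subject_log2fc)
  }

  base_fr <- vapply(types, `[[`, numeric(1), "baseline_fraction")
  blocks <- list(); ann <- list(); bc_counter <- 0L
  for (ki in seq_len(nrow(sessions))) {
    period <- sessions$period[ki]
    for (s in subjects) {
      if (!design$present[s, ki]) next
      comp <- .session_composition(base_fr, type_names,
                                   config$abundance_shift, period)
      comp <- rgamma(Tn, shape = comp * config$composition_precision)
      comp <- comp / sum(comp)
      n_by_type <- as.integer(rmultinom(1, config$cells_per_sample, comp))
      type_idx <- rep(seq_len(Tn), n_by_type)
      n <- length(type_idx)
      noise <- exp(rnorm(G, 0, config$sample_noise_sd))
      R <- rate * M * S_mult[[s]] * noise
      if (period == "PM") R <- R * D_pm
      libs <- rlnorm(n, config$library_size_log_mean,
                     config$library_size_log_sd)
      mu <- t(R)[type_idx, , drop = FALSE] * libs
      cnt <- rnbinom(length(mu), size = config$nb_dispersion, mu = mu)
      dim(cnt) <- dim(mu)
      barcodes <- sprintf("BC%07d", bc_counter + seq_len(n))
      bc_counter <- bc_counter + n
      rownames(cnt) <- barcodes
      blocks[[length(blocks) + 1L]] <- as(Matrix(cnt, sparse = TRUE),
                                          "CsparseMatrix")
      ann[[length(ann) + 1L]] <- data.frame(
        barcode = barcodes, subject = s, day = sessions$day[ki],
        session = period, sample = sessions$sample[ki],
        cell_type = type_names[type_idx], is_debris = FALSE,
        stringsAsFactors = FALSE)
    }
  }

  # debris droplets: ambient profile per session, shared across subjects
  if (!is.null(config$debris) && config$debris$n_debris_barcodes > 0) {
    sample_of_block <- vapply(ann, function(a) a$sample[1], character(1))
    for (ki in seq_len(nrow(sessions))) {
      in_session <- which(sample_of_block == sessions$sample[ki])
      if (!length(in_session)) next
      ambient <- Reduce(`+`, lapply(blocks[in_session], colSums))
      ambient <- ambient / sum(ambient)
      prof <- (1 - config$debris$ambient_mixing) * ambient +
        config$debris$ambient_mixing / G
      nd <- config$debris$n_debris_barcodes
      libs <- rlnorm(nd, config$library_size_log_mean +
                       log(config$debris$umi_scale_factor),
                     config$library_size_log_sd)
      mu <- outer(libs, prof)
      cnt <- rnbinom(length(mu), size = config$nb_dispersion, mu = mu)
      dim(cnt) <- dim(mu)
      barcodes <- sprintf("BC%07d", bc_counter + seq_len(nd))
      bc_counter <- bc_counter + nd
      rownames(cnt) <- barcodes
      blocks[[length(blocks) + 1L]] <- as(Matrix(cnt, sparse = TRUE),
                                          "CsparseMatrix")
      ann[[length(ann) + 1L]] <- data.frame(
        barcode = barcodes, subject = "unassigned",
        day = sessions$day[ki], session = sessions$period[ki],
        sample = sessions$sample[ki], cell_type = NA_character_,
        is_debris = TRUE, stringsAsFactors = FALSE)
    }
  }

  counts <- do.call(rbind, blocks)
  colnames(counts) <- gene_ids
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL

  cells <- !annotation$is_debris
  truth <- list(
    diurnal_genes = data.frame(
      gene = gene_ids[c(dg_idx, dc_idx)],
      scope = c(rep("ALL", length(dg_idx)),
                rep(config$diurnal_host, length(dc_idx))),
      direction = c(dir_dg, dir_dc), stringsAsFactors = FALSE),
    subject_genes = data.frame(
      gene = gene_ids[sj_idx], subject = sj_subject, cell_type = sj_type,
      direction = dir_sj, stringsAsFactors = FALSE),
    shifted_celltype = if (is.null(config$abundance_shift)) NA_character_
      else config$abundance_shift$cell_type,
    abundance_shift = config$abundance_shift,
    debris_barcodes = annotation$barcode[annotation$is_debris],
    celltype_of_barcode = setNames(annotation$cell_type[cells],
                                   annotation$barcode[cells]))

  structure(list(counts = counts, features = features,
                 annotation = annotation, design = design,
                 truth = truth, config = config),
            class = "capblood_sim")
}

#' @export
print.capblood_sim <- function(x, ...) {
  cat("capblood_sim:", nrow(x$counts), "barcodes x", ncol(x$counts),
      "genes;", sum(x$annotation$is_debris), "debris barcodes;",
      nrow(x$truth$diurnal_genes), "planted diurnal and",
      nrow(x$truth$subject_genes), "planted subject-specific genes\n")
  invisible(x)
}
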
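#' Preset simulation scenarios
#'
#' Frozen [sim_config()] presets for the validation experiments the package
#' ships: each emulates one aspect of the study design at a problem size
#' chosen for desk-scale runtimes (the vignette discusses the scaling).
#' They are used by both the test suite and the acceptance script so that
#' the study conditions are defined in exactly one place.
#'
#' * `scenario_null()` — no planted effects of any kind (marker elevation
#'   included), 2000 genes, 4 subjects x 6 sessions, 60 cells per
#'   subject-session: the null for type-I-error evaluation of all three
#'   testing procedures.
#' * `scenario_recovery()` — planted effects at the default sizes (log2FC
#'   2; 20 global diurnal, 20 B-cell-restricted diurnal, 20
#'   subject-specific genes), 2000 genes, 400 cells per subject-session,
#'   no abundance shift. The B-cell host is ~10% of cells, so restricted
#'   genes should be detected per-type but diluted out of the pooled test.
#' * `scenario_confound()` — the abundance-shift false-positive scenario:
#'   no expression changes at all, but B-cell abundance shifts from 10%
#'   (AM) to 16% (PM); strongly B-dominant genes (marker log2FC 6, like
#'   the published EAF2 case) should be flagged by the pooled test only.
#' * `scenario_debris()` — one study day with 300 debris droplets per
#'   session planted at the default debris profile.
#' * `scenario_typing()` — six-type mixture with the default marker panel
#'   for end-to-end typing evaluation.
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_null <- function(seed = 1L) {
  sim_config(n_genes = 2000, cells_per_sample = 60,
             cell_types = .flat_types(),
             n_diurnal_global = 0, n_diurnal_celltype = 0,
             n_subject_specific = 0, debris = NULL, seed = seed)
}

#' @rdname scenarios
#' @export
scenario_recovery <- function(seed = 1L) {
  sim_config(n_genes = 2000, cells_per_sample = 400, debris = NULL,
             seed = seed)
}

#' @rdname scenarios
#' @export
scenario_confound <- function(seed = 1L) {
  sim_config(n_genes = 300, cells_per_sample = 800,
             cell_types = .dominant_types(),
             n_diurnal_global = 0, n_diurnal_celltype = 0,
             n_subject_specific = 0, debris = NULL,
             abundance_shift = list(cell_type = "B cells",
                                    am_fraction = 0.10,
                                    pm_fraction = 0.16),
             seed = seed)
}

#' @rdname scenarios
#' @export
scenario_debris <- function(seed = 1L) {
  sim_config(n_days = 1, n_genes = 300, cells_per_sample = 120,
             n_diurnal_global = 0, n_diurnal_celltype = 0,
             n_subject_specific = 0,
             debris = debris_spec(n_debris_barcodes = 300), seed = seed)
}

#' @rdname scenarios
#' @export
scenario_typing <- function(seed = 1L) {
  sim_config(n_genes = 600, cells_per_sample = 100,
             n_diurnal_global = 0, n_diurnal_celltype = 0,
             n_subject_specific = 0, debris = NULL, seed = seed)
}

# types with no marker elevation: fully exchangeable null
.flat_types <- function() {
  lapply(default_cell_types(), function(s) { s$marker_log2fc <- 0; s })
}

# strongly type-dominant markers (EAF2-like B-restricted expression)
.dominant_types <- function() {
  lapply(default_cell_types(), function(s) { s$marker_log2fc <- 6; s })
}
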
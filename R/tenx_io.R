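#' Write a count matrix as a 10x-style directory
#'
#' Emits `matrix.mtx` (Matrix Market coordinate integer, genes x barcodes as
#' in the 10x v2 layout), `barcodes.tsv`, `features.tsv` (id, symbol,
#' type), and — when an annotation is supplied — `metadata.tsv` with
#' columns `barcode`, `subject`, `day`, `session`.
#'
#' @param counts Sparse barcodes x genes count matrix with dimnames.
#' @param path Output directory (created if needed).
#' @param features Optional data.frame with columns `id`, `symbol`;
#'   defaults to the matrix column names for both.
#' @param annotation Optional per-barcode annotation data.frame.
#' @return `path`, invisibly.
#' @export
write_tenx_dir <- function(counts, path, features = NULL, annotation = NULL) {
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    .cb_stop(paste("cannot create directory", path), "capblood_io_error")
  if (!is.null(annotation) &&
      !setequal(annotation$barcode, rownames(counts)))
    .cb_stop("annotation and matrix barcode sets differ", "capblood_io_error")
  m <- as(Matrix::t(counts), "TsparseMatrix")  # genes x barcodes on disk
  con <- file(file.path(path, "matrix.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "%",
               paste(nrow(m), ncol(m), length(m@x))), con)
  if (length(m@x))
    write.table(data.frame(m@i + 1L, m@j + 1L, as.integer(m@x)),
                con, sep = " ", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  close(con)
  writeLines(as.character(rownames(counts)), file.path(path, "barcodes.tsv"))
  if (is.null(features))
    features <- data.frame(id = colnames(counts), symbol = colnames(counts))
  write.table(cbind(features$id, features$symbol, "Gene Expression"),
              file.path(path, "features.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(annotation))
    write.table(annotation[, c("barcode", "subject", "day", "session")],
                file.path(path, "metadata.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 10x-style directory into a barcodes x genes count matrix
#'
#' On-disk 10x matrices are genes x barcodes; the matrix is transposed on
#' read so that all in-memory matrices in this package are barcodes x genes.
#' Gene identity is keyed by the feature id column; the symbol column is
#' carried as a display name in the `features` attribute.
#'
#' @param path Directory containing `matrix.mtx`, `barcodes.tsv` and
#'   `features.tsv` (optionally gzipped).
#' @return Sparse dgCMatrix (barcodes x genes) with a `features` attribute.
#' @export
read_tenx_dir <- function(path) {
  fp <- function(nm) {
    for (cand in c(file.path(path, nm), file.path(path, paste0(nm, ".gz"))))
      if (file.exists(cand)) return(cand)
    .cb_stop(paste("missing", nm, "in", path), "capblood_format_error")
  }
  m <- Matrix::readMM(fp("matrix.mtx"))
  barcodes <- readLines(fp("barcodes.tsv"))
  feat <- read.delim(fp("features.tsv"), header = FALSE,
                     stringsAsFactors = FALSE)
  if (nrow(m) != nrow(feat) || ncol(m) != length(barcodes))
    .cb_stop("matrix dimensions do not match barcode/feature lists",
             "capblood_format_error")
  if (any(m@x != round(m@x)) || any(m@x < 0))
    .cb_stop("matrix entries must be nonnegative integers",
             "capblood_format_error")
  if (anyDuplicated(barcodes) || anyDuplicated(feat[[1]]))
    .cb_stop("duplicate barcode or gene identifiers",
             "capblood_format_error")
  counts <- as(Matrix::t(m), "CsparseMatrix")
  dimnames(counts) <- list(barcodes, feat[[1]])
  attr(counts, "features") <- data.frame(
    id = feat[[1]],
    symbol = if (ncol(feat) >= 2) feat[[2]] else feat[[1]],
    stringsAsFactors = FALSE)
  counts
}

#' Read per-barcode metadata and derive the sample design
#'
#' The metadata TSV must have columns `barcode`, `subject`, `day`,
#' `session` (session in `{AM, PM}`). Matrix barcodes absent from the
#' metadata are kept and marked `"unassigned"`; metadata barcodes absent
#' from the matrix are dropped with a warning.
#'
#' @param path Path to the metadata TSV.
#' @param counts Barcodes x genes count matrix the metadata refers to.
#' @return List with `annotation` (one row per matrix barcode, columns
#'   `barcode`, `subject`, `day`, `session`, `sample`, `cell_type`,
#'   `is_debris`) and `design` ([sample_design()]).
#' @export
read_metadata <- function(path, counts) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("barcode", "subject", "day", "session")
  if (!all(need %in% names(md)))
    .cb_stop("metadata must have columns barcode, subject, day, session",
             "capblood_format_error")
  if (!all(md$session %in% c("AM", "PM")))
    .cb_stop("session values must be AM or PM", "capblood_format_error")
  extra <- !md$barcode %in% rownames(counts)
  if (any(extra)) {
    warning(sum(extra), " metadata barcode(s) not in matrix; ignored")
    md <- md[!extra, , drop = FALSE]
  }
  i <- match(rownames(counts), md$barcode)
  annotation <- data.frame(
    barcode = rownames(counts),
    subject = ifelse(is.na(i), "unassigned", md$subject[i]),
    day = md$day[i], session = md$session[i],
    stringsAsFactors = FALSE)
  annotation$sample <- ifelse(is.na(annotation$day), NA_character_,
                              paste0("D", annotation$day, "_",
                                     annotation$session))
  annotation$cell_type <- NA_character_
  annotation$is_debris <- FALSE
  list(annotation = annotation, design = design_from_annotation(annotation))
}
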
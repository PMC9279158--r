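# ---------------------------------------------------------------------------
# Readers/writers.  MTX is 1-based per the MatrixMarket standard (handled by
# Matrix::readMM/writeMM); TSVs are tab-delimited with a header row.
# Round-trip write -> read is identity; readers never reorder silently.
# ---------------------------------------------------------------------------

read_tsv_strict <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, quote = "")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
}

#' Read a single-cell dataset (MatrixMarket + metadata TSVs)
#'
#' The MTX file holds genes as rows and cells as columns; `genes_tsv` and
#' `cells_tsv` must have exactly one row per matrix row/column, in order.
#'
#' @param mtx_path path to a MatrixMarket `.mtx` file of UMI counts.
#' @param cells_tsv path to a TSV of cell metadata (`cell_id`, `sample_id`,
#'   `patient_id`, `cohort_id`, `tissue`, optional truth columns).
#' @param genes_tsv path to a TSV of gene metadata (at least `gene_id`).
#' @return An [sc_counts()] object.
#' @export
read_sc_dataset <- function(mtx_path, cells_tsv, genes_tsv) {
  m <- Matrix::readMM(mtx_path)
  cells <- read_tsv_strict(cells_tsv)
  genes <- read_tsv_strict(genes_tsv)
  if (nrow(cells) != ncol(m))
    stop("cells TSV has ", nrow(cells), " rows but matrix has ", ncol(m), " columns")
  if (nrow(genes) != nrow(m))
    stop("genes TSV has ", nrow(genes), " rows but matrix has ", nrow(m), " rows")
  if (all(c("chromosome", "arm", "start_bp", "is_mito") %in% names(genes)))
    genes <- gene_annotation(genes)
  for (col in c("is_doublet", "is_low_quality")) # truth columns, if present
    if (!is.null(cells[[col]])) cells[[col]] <- as.logical(cells[[col]])
  sc_counts(m, cells, genes)
}

#' Write a single-cell dataset to a directory
#'
#' Emits `matrix.mtx`, `cells.tsv`, `genes.tsv` in the layout
#' [read_sc_dataset()] expects.
#'
#' @param x an `sc_counts` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_sc_dataset <- function(x, dir) {
  stopifnot(inherits(x, "sc_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  write_tsv(x$cells, file.path(dir, "cells.tsv"))
  write_tsv(as.data.frame(x$genes), file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' Read a directional signature from TSV
#'
#' Expects columns `gene`, `class`, `direction` (direction in {"Up","Down"},
#' case as written).  Duplicate rows are collapsed.
#'
#' @param tsv_path path to the signature TSV.
#' @param provenance provenance note stored on the result.
#' @return A [signature_set()].
#' @export
read_signature <- function(tsv_path, provenance = tsv_path) {
  df <- read_tsv_strict(tsv_path)
  if (!all(c("gene", "class", "direction") %in% names(df)))
    stop("signature TSV must have columns gene, class, direction")
  bad <- setdiff(unique(df$direction), c("Up", "Down"))
  if (length(bad)) stop("direction outside {Up, Down}: ", paste(bad, collapse = ", "))
  df <- unique(df[, c("gene", "class", "direction")])
  sets <- lapply(split(df, df$class), function(d)
    list(up = d$gene[d$direction == "Up"], down = d$gene[d$direction == "Down"]))
  signature_set(sets, provenance = provenance)
}

#' Write a signature set to TSV
#' @param sig a `signature_set`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_signature <- function(sig, path) {
  rows <- do.call(rbind, lapply(names(sig$sets), function(cl) {
    s <- sig$sets[[cl]]
    rbind(
      if (length(s$up)) data.frame(gene = s$up, class = cl, direction = "Up"),
      if (length(s$down)) data.frame(gene = s$down, class = cl, direction = "Down")
    )
  }))
  write_tsv(rows, path)
  invisible(path)
}

#' Read a bulk expression matrix (genes x samples TSV) with optional labels
#'
#' The first column of `tsv_path` holds gene ids; remaining columns are
#' samples.  `labels_tsv`, if given, is joined by `sample_id`; samples
#' without a label row get "unknown".
#'
#' @param tsv_path path to the expression TSV (log scale).
#' @param labels_tsv optional TSV with `sample_id` and any of `msi`, `cms`,
#'   `cohort_id`.
#' @return A [bulk_matrix()].
#' @export
read_bulk_matrix <- function(tsv_path, labels_tsv = NULL) {
  df <- read_tsv_strict(tsv_path)
  gene_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in bulk matrix")
  rownames(m) <- gene_ids
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in bulk matrix header")
  samples <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  if (!is.null(labels_tsv)) {
    lab <- read_tsv_strict(labels_tsv)
    if (anyDuplicated(lab$sample_id)) stop("duplicate sample ids in labels TSV")
    idx <- match(samples$sample_id, lab$sample_id)
    for (col in setdiff(names(lab), "sample_id"))
      samples[[col]] <- lab[[col]][idx]
  }
  bulk_matrix(m, samples)
}

#' Write a bulk matrix (+ labels) to TSV
#' @param x a `bulk_matrix`.
#' @param tsv_path output expression TSV path.
#' @param labels_tsv optional output path for the sample label TSV.
#' @return invisibly, `tsv_path`.
#' @export
write_bulk_matrix <- function(x, tsv_path, labels_tsv = NULL) {
  df <- data.frame(gene_id = rownames(x$expr), x$expr, check.names = FALSE)
  write_tsv(df, tsv_path)
  if (!is.null(labels_tsv)) write_tsv(x$samples, labels_tsv)
  invisible(tsv_path)
}

#' Read a gene annotation table (BED-like TSV)
#'
#' Columns: `chromosome`, `start_bp`, `gene_id`, `arm`, `is_mito`
#' (header row required; extra columns such as `symbol` carried along).
#'
#' @param tsv_path path to the annotation TSV.
#' @return A [gene_annotation()].
#' @export
read_gene_annotation <- function(tsv_path) {
  gene_annotation(read_tsv_strict(tsv_path))
}

#' Write a gene annotation table to TSV
#' @param genes a `gene_annotation`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_annotation <- function(genes, path) {
  write_tsv(as.data.frame(genes), path)
  invisible(path)
}
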
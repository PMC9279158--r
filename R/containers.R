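#' @importFrom methods as is new
#' @importFrom stats prcomp kmeans hclust cutree dist median quantile sd var
#'   rnbinom rlnorm rnorm runif rbinom rmultinom p.adjust phyper pnorm pt
#'   wilcox.test as.dist cor setNames complete.cases coef glm poisson dnbinom
#'   optimize glm.control fitted ave rbeta
#' @importFrom utils read.delim write.table head
NULL

# ---------------------------------------------------------------------------
# Typed containers used across the pipeline.  All single-cell matrices are
# stored genes x cells (the CellRanger / Bioconductor convention); bulk
# matrices are genes x samples.
# ---------------------------------------------------------------------------

#' Construct a gene annotation table
#'
#' Per-gene genomic annotation: chromosome, arm, start position and a
#' mitochondrial flag.  Genes must be uniquely identified and map to exactly
#' one (chromosome, arm).
#'
#' @param df data.frame with columns `gene_id`, `chromosome`, `arm` (one of
#'   "p"/"q"), `start_bp` (integer >= 0), `is_mito` (logical).  An optional
#'   `symbol` column is carried along.
#' @return A validated `gene_annotation` data.frame.
#' @export
gene_annotation <- function(df) {
  req <- c("gene_id", "chromosome", "arm", "start_bp", "is_mito")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("gene annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in gene annotation")
  if (!all(df$arm %in% c("p", "q"))) stop("arm must be 'p' or 'q'")
  if (any(df$start_bp < 0)) stop("start_bp must be >= 0")
  df$is_mito <- as.logical(df$is_mito)
  df$start_bp <- as.integer(df$start_bp)
  rownames(df) <- df$gene_id
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Chromosome-arm label for annotated genes
#'
#' @param genes a `gene_annotation` data.frame.
#' @return character vector like "8q", "17p" (chromosome pasted to arm).
#' @export
arm_label <- function(genes) paste0(genes$chromosome, genes$arm)

#' Construct a single-cell count matrix container
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts
#'   (dense or sparse; stored as `dgCMatrix`).
#' @param cells data.frame of cell metadata with at least `cell_id`,
#'   `sample_id`, `patient_id`, `cohort_id`, `tissue`; one row per column of
#'   `counts`, in order.
#' @param genes gene metadata (ideally a [gene_annotation()]) with `gene_id`;
#'   one row per row of `counts`, in order.
#' @return An `sc_counts` object (list with elements `counts`, `cells`,
#'   `genes`).
#' @export
sc_counts <- function(counts, cells, genes) {
  if (!inherits(counts, "Matrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(cells) != ncol(counts))
    stop("cell metadata rows (", nrow(cells), ") != count matrix columns (", ncol(counts), ")")
  if (nrow(genes) != nrow(counts))
    stop("gene metadata rows (", nrow(genes), ") != count matrix rows (", nrow(counts), ")")
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  v <- counts@x
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (!all(c("cell_id", "sample_id", "patient_id", "cohort_id", "tissue") %in% names(cells)))
    stop("cell metadata must contain cell_id, sample_id, patient_id, cohort_id, tissue")
  bad <- setdiff(unique(cells$tissue), c("tumor", "normal", "lymph_node"))
  if (length(bad)) stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  # sample -> patient -> cohort must be functions
  smap <- unique(cells[, c("sample_id", "patient_id", "cohort_id")])
  if (anyDuplicated(smap$sample_id)) stop("sample_id maps to more than one patient/cohort")
  dimnames(counts) <- list(genes$gene_id, cells$cell_id)
  rownames(cells) <- cells$cell_id
  structure(list(counts = counts, cells = cells, genes = genes), class = "sc_counts")
}

#' @export
print.sc_counts <- function(x, ...) {
  cat("sc_counts: ", nrow(x$counts), " genes x ", ncol(x$counts), " cells; ",
      length(unique(x$cells$sample_id)), " samples, ",
      length(unique(x$cells$patient_id)), " patients, ",
      length(unique(x$cells$cohort_id)), " cohorts\n", sep = "")
  invisible(x)
}

#' Subset an sc_counts (or sc_lognorm) object by cells and/or genes
#'
#' @param x `sc_counts` or `sc_lognorm`.
#' @param cells logical/integer/character index over cells (columns).
#' @param genes logical/integer/character index over genes (rows).
#' @return object of the same class.
#' @export
sc_subset <- function(x, cells = NULL, genes = NULL) {
  m <- if (inherits(x, "sc_counts")) "counts" else "data"
  if (!is.null(cells)) {
    if (is.character(cells)) cells <- match(cells, x$cells$cell_id)
    x[[m]] <- x[[m]][, cells, drop = FALSE]
    x$cells <- x$cells[cells, , drop = FALSE]
  }
  if (!is.null(genes)) {
    if (is.character(genes)) genes <- match(genes, x$genes$gene_id)
    x[[m]] <- x[[m]][genes, , drop = FALSE]
    x$genes <- x$genes[genes, , drop = FALSE]
  }
  x
}

#' Number of detected genes per cell
#'
#' NODG: the number of genes with a non-zero UMI count in each cell.
#'
#' @param x an `sc_counts` object or a genes x cells matrix.
#' @return integer vector, one entry per cell.
#' @export
nodg <- function(x) {
  m <- if (inherits(x, "sc_counts")) x$counts else x
  setNames(Matrix::colSums(m > 0), colnames(m))
}

#' Percent mitochondrial counts per cell
#'
#' @param x an `sc_counts` object whose gene table has `is_mito`.
#' @return numeric vector of percentages in [0, 100].
#' @export
pct_mito <- function(x) {
  stopifnot(inherits(x, "sc_counts"))
  if (is.null(x$genes$is_mito)) stop("gene annotation lacks is_mito flag")
  tot <- Matrix::colSums(x$counts)
  mt <- Matrix::colSums(x$counts[x$genes$is_mito, , drop = FALSE])
  100 * ifelse(tot > 0, mt / tot, 0)
}

#' Construct a directional signature set
#'
#' A mapping class -> {Up, Down} gene sets, the shape of the 848-gene
#' stage-one and 715-gene final iCMS signatures.
#'
#' @param sets named list; each element a list with character vectors `up`
#'   and `down`.  Within a class, up and down must be disjoint.
#' @param provenance free-text provenance note.
#' @return A `signature_set` object.
#' @export
signature_set <- function(sets, provenance = "") {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("signature classes must be named")
  sets <- lapply(sets, function(s) {
    up <- unique(as.character(s$up %||% character()))
    dn <- unique(as.character(s$down %||% character()))
    ov <- intersect(up, dn)
    if (length(ov))
      stop("gene(s) in both Up and Down of one class: ", paste(head(ov, 3), collapse = ", "))
    list(up = up, down = dn)
  })
  structure(list(sets = sets, provenance = provenance), class = "signature_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set with", length(x$sets), "classes:\n")
  for (cl in names(x$sets))
    cat("  ", cl, ": ", length(x$sets[[cl]]$up), " up, ",
        length(x$sets[[cl]]$down), " down\n", sep = "")
  invisible(x)
}

#' All genes referenced by a signature set
#' @param sig a `signature_set`.
#' @return character vector of unique gene ids.
#' @export
signature_genes <- function(sig) {
  unique(unlist(lapply(sig$sets, function(s) c(s$up, s$down)), use.names = FALSE))
}

#' Construct a bulk expression matrix container
#'
#' @param expr genes x samples numeric matrix on log scale; finite values.
#' @param samples data.frame with `sample_id` plus optional `msi`
#'   ("MSI-H"/"MSS"/"unknown"), `cms` ("CMS1".."CMS4"/"unknown"),
#'   `cohort_id`.  Missing label columns are filled with "unknown".
#' @return A `bulk_matrix` object.
#' @export
bulk_matrix <- function(expr, samples = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("bulk matrix must have gene ids as rownames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids in bulk matrix")
  if (!all(is.finite(expr))) stop("bulk matrix contains non-finite values")
  if (is.null(samples)) samples <- data.frame(sample_id = colnames(expr))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop("sample metadata does not cover all samples")
  for (col in c("msi", "cms", "cohort_id")) {
    if (is.null(samples[[col]])) samples[[col]] <- "unknown"
    samples[[col]][is.na(samples[[col]])] <- "unknown"
  }
  bad <- setdiff(unique(samples$msi), c("MSI-H", "MSS", "unknown"))
  if (length(bad)) stop("invalid msi label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$cms), c(paste0("CMS", 1:4), "unknown"))
  if (length(bad)) stop("invalid cms label(s): ", paste(bad, collapse = ", "))
  rownames(samples) <- samples$sample_id
  structure(list(expr = expr, samples = samples), class = "bulk_matrix")
}

#' @export
print.bulk_matrix <- function(x, ...) {
  cat("bulk_matrix:", nrow(x$expr), "genes x", ncol(x$expr), "samples\n")
  invisible(x)
}
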
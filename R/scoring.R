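# ---------------------------------------------------------------------------
# Metagene scoring: per-cohort z-scaling, set averages, score-difference
# cell classification with a bimodality check, marker-to-cell-type
# assignment (the eCMS construction) and bulk cell-type metagenes.
# ---------------------------------------------------------------------------

#' Zero-center and unit-scale each gene within each cohort
#'
#' @param mat genes x entities numeric matrix (dense or sparse).
#' @param cohorts per-entity cohort labels (single cohort allowed).
#' @return dense matrix of the same shape; zero-variance genes are set to 0
#'   and listed in attribute `zero_variance` (per cohort).
#' @export
zscore_within_cohort <- function(mat, cohorts = rep("all", ncol(mat))) {
  if (length(cohorts) != ncol(mat)) stop("cohort labels must match columns")
  sizes <- table(cohorts)
  if (any(sizes < 2)) stop("cohort(s) with a single entity: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  out <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  zv <- list()
  for (co in unique(cohorts)) {
    idx <- which(cohorts == co)
    z <- scale_rows(as.matrix(mat[, idx, drop = FALSE]))
    out[, idx] <- z
    zv[[co]] <- attr(z, "zero_variance")
  }
  attr(out, "zero_variance") <- zv
  out
}

#' Metagene score: mean scaled expression over a gene set
#'
#' @param scaled genes x entities z-scored matrix.
#' @param gene_set character vector of gene ids; genes absent from the
#'   matrix are ignored (the coverage fraction is recorded).
#' @param down_set optional "Down" genes for the signed variant
#'   (mean Up - mean Down).
#' @return numeric score per entity, with attribute `coverage`.
#' @export
metagene_score <- function(scaled, gene_set, down_set = NULL) {
  present <- intersect(gene_set, rownames(scaled))
  if (!length(present)) stop("zero coverage: no signature gene in matrix")
  s <- colMeans(scaled[present, , drop = FALSE])
  cov <- length(present) / length(gene_set)
  if (!is.null(down_set) && length(down_set)) {
    pd <- intersect(down_set, rownames(scaled))
    if (length(pd)) {
      s <- s - colMeans(scaled[pd, , drop = FALSE])
      cov <- (length(present) + length(pd)) / (length(gene_set) + length(down_set))
    }
  }
  attr(s, "coverage") <- cov
  s
}

#' Classify cells by iCMS metagene score difference
#'
#' Preferential i2 when `i2 - i3 > delta`, preferential i3 when
#' `i3 - i2 > delta`, else ambiguous (a difference of exactly `delta` is
#' ambiguous).  A tumor is flagged hybrid when fewer than `majority_frac`
#' of its cells are preferential for one single type.  Bimodality of the
#' score difference is assessed by comparing 1- and 2-component Gaussian
#' mixtures by BIC.
#'
#' @param i2_score,i3_score per-cell metagene scores (same cells).
#' @param delta score-difference threshold (default 0.1, z-score units).
#' @param tumor optional per-cell tumor/patient labels for the hybrid flag.
#' @param majority_frac single-type majority required for a non-hybrid
#'   tumor (default 0.8).
#' @return list with per-cell `call`, per-tumor `composition` (fractions
#'   and `hybrid` flag) and `bimodality` (`n_components`, BIC values).
#' @export
classify_cells_by_score <- function(i2_score, i3_score, delta = 0.1,
                                    tumor = NULL, majority_frac = 0.8) {
  if (length(i2_score) != length(i3_score)) stop("score lengths differ")
  d <- i2_score - i3_score
  call <- ifelse(d > delta, "preferential_i2",
                 ifelse(-d > delta, "preferential_i3", "ambiguous"))
  names(call) <- names(i2_score)
  comp <- NULL
  if (!is.null(tumor)) {
    comp <- do.call(rbind, lapply(split(call, tumor), function(v) {
      f2 <- mean(v == "preferential_i2"); f3 <- mean(v == "preferential_i3")
      data.frame(frac_i2 = f2, frac_i3 = f3, frac_ambiguous = 1 - f2 - f3,
                 hybrid = max(f2, f3) < majority_frac)
    }))
    comp$tumor <- rownames(comp)
  }
  bic <- tryCatch({
    fit <- mclust::mclustBIC(d, G = 1:2, modelNames = "V", verbose = FALSE)
    b1 <- max(fit[1, ], na.rm = TRUE); b2 <- max(fit[2, ], na.rm = TRUE)
    list(n_components = if (b2 > b1) 2L else 1L, bic_1 = b1, bic_2 = b2)
  }, error = function(e) list(n_components = NA_integer_,
                              bic_1 = NA_real_, bic_2 = NA_real_))
  list(call = call, composition = comp, bimodality = bic,
       score_difference = d)
}

#' Assign marker genes to cell types by pseudo-bulk argmax
#'
#' The cell-type pseudo-bulk is the mean over patients of per-patient mean
#' log-normalised profiles.  Each marker gene is assigned to the cell type
#' in which it is highest; the epithelial-specific subset per class (the
#' eCMS construction) is the set of markers whose maximum is epithelial.
#'
#' @param lognorm an `sc_lognorm`.
#' @param cell_types per-cell type labels (named by cell id, or in order).
#' @param marker_sets named list of gene-id vectors (e.g. CMS marker sets).
#' @param epithelial_label name of the epithelial type (default
#'   "epithelial").
#' @return list with `assignment` (data.frame gene/set/cell_type/tied),
#'   `epithelial_specific` (list per set) and the `celltype_pseudobulk`
#'   matrix.
#' @export
assign_markers_to_celltypes <- function(lognorm, cell_types, marker_sets,
                                        epithelial_label = "epithelial") {
  stopifnot(inherits(lognorm, "sc_lognorm"))
  ct <- if (!is.null(names(cell_types))) cell_types[colnames(lognorm$data)] else cell_types
  pat <- lognorm$cells$patient_id
  types <- sort(unique(ct[!is.na(ct) & ct != "unassigned"]))
  # per-patient per-type means, then average across patients
  pb <- sapply(types, function(t) {
    per_pat <- sapply(unique(pat), function(p) {
      idx <- which(ct == t & pat == p)
      if (!length(idx)) return(rep(NA_real_, nrow(lognorm$data)))
      Matrix::rowMeans(lognorm$data[, idx, drop = FALSE])
    })
    rowMeans(per_pat, na.rm = TRUE)
  })
  rownames(pb) <- lognorm$genes$gene_id
  rows <- do.call(rbind, lapply(names(marker_sets), function(nm) {
    genes <- intersect(marker_sets[[nm]], rownames(pb))
    if (!length(genes)) return(NULL)
    sub <- pb[genes, , drop = FALSE]
    best <- apply(sub, 1, function(v) {
      w <- which(v == max(v, na.rm = TRUE))
      c(colnames(sub)[w[1]], length(w) > 1)  # deterministic tie-break
    })
    data.frame(gene_id = genes, set = nm, cell_type = best[1, ],
               tied = as.logical(best[2, ]), stringsAsFactors = FALSE)
  }))
  epi <- lapply(split(rows, rows$set), function(d)
    d$gene_id[d$cell_type == epithelial_label])
  list(assignment = rows, epithelial_specific = epi, celltype_pseudobulk = pb)
}

#' Bulk cell-type metagene scores
#'
#' One mean-scaled-expression score per (sample, cell type); the bulk
#' matrix must already be z-scored per dataset.
#'
#' @param bulk_z genes x samples z-scored matrix.
#' @param celltype_sets named list of cell-type marker gene vectors.
#' @param min_coverage warn when a set's coverage falls below this
#'   fraction (default 0.2).
#' @return samples x cell-type score matrix.
#' @export
bulk_celltype_metagenes <- function(bulk_z, celltype_sets, min_coverage = 0.2) {
  out <- sapply(names(celltype_sets), function(nm) {
    s <- metagene_score(bulk_z, celltype_sets[[nm]])
    if (attr(s, "coverage") < min_coverage)
      warning("set ", nm, " coverage below ", min_coverage)
    s
  })
  rownames(out) <- colnames(bulk_z)
  out
}
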
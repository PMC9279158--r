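# ---------------------------------------------------------------------------
# Three-round QC: empty-droplet removal, log-normalisation, reference-
# correlation cell typing, sample-level median-of-medians QC, pANN doublet
# detection, and cell-type-specific NODG/mito cutoffs.  Each stage only
# removes cells, never edits counts.
# ---------------------------------------------------------------------------

#' QC thresholds
#'
#' @param min_nodg_empty cells with NODG strictly below this are discarded
#'   as empty droplets (default 300).
#' @param sample_deviation_factor a sample "deviates" for a cell type when
#'   its median NODG differs from the across-sample reference by a factor
#'   strictly greater than this, in either direction (default 2).
#' @param celltype_cutoffs data.frame with columns `cell_type`, `min_nodg`,
#'   `max_mito_pct`; a row with cell_type "default" supplies the fallback.
#'   Defaults: epithelial NODG >= 1000, mito <= 20%; others NODG >= 500,
#'   mito <= 25%.
#' @param doublet_rate_per_1000 expected doublet percentage per 1,000
#'   recovered cells (default 0.8, the 10x linear rule).
#' @param pann_k number of nearest neighbours for pANN; NULL means
#'   `round(0.01 * n_cells)` per sample.
#' @param pann_artificial_frac fraction of the merged data made of
#'   artificial doublets (pN, default 0.25).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_nodg_empty = 300L,
                          sample_deviation_factor = 2,
                          celltype_cutoffs = NULL,
                          doublet_rate_per_1000 = 0.8,
                          pann_k = NULL,
                          pann_artificial_frac = 0.25) {
  if (is.null(celltype_cutoffs)) {
    celltype_cutoffs <- data.frame(
      cell_type = c("epithelial", "default"),
      min_nodg = c(1000L, 500L),
      max_mito_pct = c(20, 25),
      stringsAsFactors = FALSE)
  }
  if (!"default" %in% celltype_cutoffs$cell_type)
    stop("celltype_cutoffs must cover every annotated type or supply a 'default' row")
  stopifnot(min_nodg_empty > 0, sample_deviation_factor > 0,
            all(celltype_cutoffs$min_nodg > 0),
            all(celltype_cutoffs$max_mito_pct > 0))
  structure(list(min_nodg_empty = min_nodg_empty,
                 sample_deviation_factor = sample_deviation_factor,
                 celltype_cutoffs = celltype_cutoffs,
                 doublet_rate_per_1000 = doublet_rate_per_1000,
                 pann_k = pann_k,
                 pann_artificial_frac = pann_artificial_frac),
            class = "qc_thresholds")
}

#' Remove empty droplets
#'
#' Retains cells with NODG >= `min_nodg`; strictly smaller NODG is
#' discarded.
#'
#' @param counts an [sc_counts()].
#' @param min_nodg integer threshold (default 300).
#' @return filtered `sc_counts`.
#' @export
filter_empty_droplets <- function(counts, min_nodg = 300L) {
  keep <- nodg(counts) >= min_nodg
  sc_subset(counts, cells = which(keep))
}

#' Depth-normalise and log-transform UMI counts
#'
#' Each cell is scaled to a fixed total (default 10,000 UMIs) and
#' log-transformed with a pseudocount of 1:
#' `value = log(1 + count * scale_factor / cell_total)`.
#'
#' @param counts an [sc_counts()]; every cell must have at least one count.
#' @param scale_factor target total per cell (default 1e4).
#' @return an `sc_lognorm` object (`data`, `cells`, `genes`, `scale_factor`,
#'   `pseudocount`).
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  stopifnot(inherits(counts, "sc_counts"))
  tot <- Matrix::colSums(counts$counts)
  if (any(tot == 0)) stop("cell(s) with zero total counts: ",
                          paste(head(colnames(counts$counts)[tot == 0], 3), collapse = ", "))
  m <- counts$counts
  m@x <- log1p(m@x * scale_factor / rep.int(tot, diff(m@p)))
  structure(list(data = m, cells = counts$cells, genes = counts$genes,
                 scale_factor = scale_factor, pseudocount = 1),
            class = "sc_lognorm")
}

#' @export
print.sc_lognorm <- function(x, ...) {
  cat("sc_lognorm:", nrow(x$data), "genes x", ncol(x$data), "cells (scale",
      x$scale_factor, ")\n")
  invisible(x)
}

#' Assign major cell types by reference-correlation projection
#'
#' Each cell is projected onto reference transcriptomes by Pearson
#' correlation over shared genes; cells are clustered in that projection
#' space (SNN graph + Louvain) and each cluster is labelled by the
#' reference with the highest median correlation.  Cells with zero variance
#' over shared genes are "unassigned".
#'
#' @param lognorm an `sc_lognorm`.
#' @param reference_profiles genes x cell-type numeric matrix (log scale);
#'   at least 2 types and 50 shared genes required.
#' @param resolution Louvain resolution (default 0.2).
#' @param k SNN neighbours (default 20).
#' @param seed RNG seed for the graph clustering.
#' @return list with `cell_type` (per cell, via its cluster's label),
#'   `cell_type_argmax` (per cell, by its own best-correlated reference),
#'   `max_correlation`, `cluster`, `cluster_label` and the per-cluster
#'   median correlation `profile`.
#' @export
assign_major_cell_types <- function(lognorm, reference_profiles,
                                    resolution = 0.5, k = 20L, seed = 1L) {
  stopifnot(inherits(lognorm, "sc_lognorm"))
  if (ncol(reference_profiles) < 2) stop("reference must have >= 2 cell types")
  shared <- intersect(rownames(reference_profiles), lognorm$genes$gene_id)
  if (length(shared) < 50) stop("fewer than 50 genes shared with the reference")
  X <- as.matrix(lognorm$data[match(shared, lognorm$genes$gene_id), , drop = FALSE])
  R <- reference_profiles[shared, , drop = FALSE]
  keep <- apply(X, 2, sd) > 0
  proj <- matrix(NA_real_, ncol(X), ncol(R),
                 dimnames = list(colnames(X), colnames(R)))
  proj[keep, ] <- cor(X[, keep, drop = FALSE], R)
  cl <- rep(NA_integer_, ncol(X))
  cl[keep] <- snn_louvain(proj[keep, , drop = FALSE], k = k,
                          resolution = resolution, seed = seed)
  labels <- vapply(sort(unique(cl[keep])), function(g) {
    med <- apply(proj[which(keep)[cl[keep] == g], , drop = FALSE], 2, median)
    colnames(R)[which.max(med)]
  }, character(1))
  type <- rep("unassigned", ncol(X))
  type[keep] <- labels[cl[keep]]
  maxcor <- rep(NA_real_, ncol(X))
  maxcor[keep] <- apply(proj[keep, , drop = FALSE], 1, max)
  prof <- t(vapply(sort(unique(cl[keep])), function(g)
    apply(proj[which(keep)[cl[keep] == g], , drop = FALSE], 2, median),
    numeric(ncol(R))))
  rownames(prof) <- labels
  # per-cell argmax projection type: unlike cluster labels it cannot be
  # masked by sample-wide artefacts (a degraded sample clusters by itself),
  # so the sample-QC stage relies on it
  argmax <- rep("unassigned", ncol(X))
  argmax[keep] <- colnames(R)[apply(proj[keep, , drop = FALSE], 1, which.max)]
  list(cell_type = setNames(type, colnames(X)),
       cell_type_argmax = setNames(argmax, colnames(X)),
       max_correlation = setNames(maxcor, colnames(X)),
       cluster = setNames(cl, colnames(X)),
       cluster_label = labels, profile = prof)
}

#' Flag low-quality samples by the median-of-medians NODG rule
#'
#' For each cell type, the reference NODG is the median over samples of the
#' per-sample median NODG.  A sample deviates for a cell type when its
#' median differs from the reference by a factor strictly greater than
#' `sample_deviation_factor` in either direction; samples deviating in more
#' than half of the cell types they could be evaluated on are discarded.
#' Cell types absent from a sample are excluded from both the deviation
#' count and the denominator.
#'
#' @param counts an [sc_counts()].
#' @param cell_types per-cell type labels (named by cell id, or in column
#'   order).
#' @param thresholds a [qc_thresholds()].
#' @return list with `discard` (sample ids), `deviations` (sample x type
#'   logical matrix) and `reference_nodg`.
#' @export
flag_low_quality_samples <- function(counts, cell_types,
                                     thresholds = qc_thresholds()) {
  stopifnot(inherits(counts, "sc_counts"))
  sam <- counts$cells$sample_id
  if (length(unique(sam)) < 2) stop("need >= 2 samples for sample-level QC")
  g <- nodg(counts)
  ct <- if (!is.null(names(cell_types)))
    cell_types[counts$cells$cell_id] else cell_types
  types <- sort(unique(ct[ct != "unassigned" & !is.na(ct)]))
  samples <- sort(unique(sam))
  med <- matrix(NA_real_, length(samples), length(types),
                dimnames = list(samples, types))
  for (t in types) for (s in samples) {
    v <- g[sam == s & ct == t & !is.na(ct)]
    if (length(v)) med[s, t] <- median(v)
  }
  ref <- apply(med, 2, median, na.rm = TRUE)
  ratio <- sweep(med, 2, ref, "/")
  f <- thresholds$sample_deviation_factor
  dev <- (ratio > f | ratio < 1 / f)
  n_eval <- rowSums(!is.na(dev))
  n_dev <- rowSums(dev, na.rm = TRUE)
  discard <- samples[n_dev > n_eval / 2]
  list(discard = discard, deviations = dev, reference_nodg = ref,
       median_nodg = med)
}

#' Detect doublets by the proportion of artificial nearest neighbours
#'
#' Per sample: artificial doublets are synthesised by averaging random
#' real-cell pairs, the merged data are embedded by PCA, each real cell is
#' scored by its proportion of artificial k-nearest neighbours (pANN), and
#' the top N cells are flagged where N follows the linear 10x rule
#' `N = round(n * (rate_per_1000 * n / 1000) / 100)`.
#'
#' @param lognorm an `sc_lognorm`.
#' @param thresholds a [qc_thresholds()].
#' @param seed RNG seed.
#' @param n_pcs PCA dimensions (default 10).
#' @param n_features top variable genes used (default 500).
#' @param min_cells samples smaller than this are skipped with a warning.
#' @return list with `doublets` (cell ids) and per-cell `pann` scores.
#' @export
detect_doublets <- function(lognorm, thresholds = qc_thresholds(), seed = 1L,
                            n_pcs = 10L, n_features = 500L, min_cells = 100L) {
  stopifnot(inherits(lognorm, "sc_lognorm"))
  set.seed(seed)
  out <- character()
  pann_all <- setNames(rep(NA_real_, ncol(lognorm$data)),
                       colnames(lognorm$data))
  for (s in unique(lognorm$cells$sample_id)) {
    idx <- which(lognorm$cells$sample_id == s)
    n <- length(idx)
    if (n < min_cells) {
      warning("sample ", s, " has fewer than ", min_cells, " cells; skipped")
      next
    }
    n_exp <- expected_doublet_count(n, thresholds$doublet_rate_per_1000)
    if (n_exp <= 0) next
    X <- lognorm$data[, idx, drop = FALSE]
    v <- rowVars_sparse(X)
    feats <- order(v, decreasing = TRUE)[seq_len(min(n_features, nrow(X)))]
    Xr <- as.matrix(X[feats, , drop = FALSE])
    pN <- thresholds$pann_artificial_frac
    n_art <- round(n * pN / (1 - pN))
    a <- sample(n, n_art, replace = TRUE)
    b <- sample(n, n_art, replace = TRUE)
    art <- (Xr[, a, drop = FALSE] + Xr[, b, drop = FALSE]) / 2
    merged <- t(cbind(Xr, art))
    pc <- prcomp(merged, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
    k <- thresholds$pann_k %||% max(2L, round(0.01 * nrow(merged)))
    nn <- knn_index(pc, k)
    is_art <- c(rep(FALSE, n), rep(TRUE, n_art))
    pann <- rowMeans(matrix(is_art[nn[seq_len(n), ]], n))
    pann_all[idx] <- pann
    flag <- order(pann, decreasing = TRUE)[seq_len(min(n_exp, n))]
    out <- c(out, colnames(Xr)[flag])
  }
  list(doublets = out, pann = pann_all)
}

#' Expected doublet count under the linear 10x rule
#'
#' The doublet rate grows linearly with the number of recovered cells:
#' `rate% = rate_per_1000 * n / 1000`, so the expected count is
#' `round(n * rate% / 100)`; e.g. 5,000 cells at 0.8 per 1,000 gives a 4%
#' rate and 200 expected doublets.
#'
#' @param n_cells recovered cells in the sample.
#' @param rate_per_1000 doublet percentage per 1,000 cells (default 0.8).
#' @return integer expected doublet count.
#' @export
expected_doublet_count <- function(n_cells, rate_per_1000 = 0.8) {
  round(n_cells * (rate_per_1000 * n_cells / 1000) / 100)
}

rowVars_sparse <- function(m) {
  mu <- Matrix::rowMeans(m)
  Matrix::rowMeans(m^2) - mu^2
}

#' Apply cell-type-specific NODG and mitochondrial cutoffs
#'
#' Retains cells with NODG >= the type's minimum and mitochondrial
#' percentage <= the type's maximum (boundary values retained).
#'
#' @param counts an [sc_counts()] with mitochondrial genes flagged.
#' @param cell_types per-cell type labels (named by cell id, or in order).
#' @param thresholds a [qc_thresholds()].
#' @return filtered `sc_counts`.
#' @export
apply_celltype_cutoffs <- function(counts, cell_types,
                                   thresholds = qc_thresholds()) {
  stopifnot(inherits(counts, "sc_counts"))
  if (is.null(counts$genes$is_mito)) stop("gene annotation lacks is_mito flag")
  ct <- if (!is.null(names(cell_types)))
    cell_types[counts$cells$cell_id] else cell_types
  tab <- thresholds$celltype_cutoffs
  i <- match(ct, tab$cell_type)
  i[is.na(i)] <- match("default", tab$cell_type)
  g <- nodg(counts)
  mt <- pct_mito(counts)
  keep <- g >= tab$min_nodg[i] & mt <= tab$max_mito_pct[i]
  sc_subset(counts, cells = which(keep))
}

#' Run the full QC pipeline
#'
#' Empty-droplet filter, log-normalisation, reference-correlation cell
#' typing, sample-level median-of-medians QC, pANN doublet removal and
#' cell-type cutoffs, in the stage order of the original analysis.
#'
#' @param counts an [sc_counts()].
#' @param reference_profiles genes x cell-type reference matrix (log scale).
#' @param thresholds a [qc_thresholds()].
#' @param seed RNG seed.
#' @return list with the QC'd `counts`, its `lognorm`, per-cell `cell_type`,
#'   and a `report` of retention counts per stage.
#' @export
run_qc <- function(counts, reference_profiles, thresholds = qc_thresholds(),
                   seed = 1L) {
  report <- list(input = ncol(counts$counts))
  counts <- filter_empty_droplets(counts, thresholds$min_nodg_empty)
  report$after_empty <- ncol(counts$counts)
  ln <- lognormalize(counts)
  typing <- assign_major_cell_types(ln, reference_profiles, seed = seed)
  bad_samples <- flag_low_quality_samples(counts, typing$cell_type_argmax,
                                          thresholds)
  keep <- !counts$cells$sample_id %in% bad_samples$discard
  counts <- sc_subset(counts, cells = which(keep))
  ln <- sc_subset(ln, cells = which(keep))
  report$after_sample_qc <- ncol(counts$counts)
  dbl <- detect_doublets(ln, thresholds, seed = seed)
  keep <- !counts$cells$cell_id %in% dbl$doublets
  counts <- sc_subset(counts, cells = which(keep))
  report$after_doublets <- ncol(counts$counts)
  counts <- apply_celltype_cutoffs(counts, typing$cell_type, thresholds)
  report$after_cutoffs <- ncol(counts$counts)
  ln <- lognormalize(counts)
  list(counts = counts, lognorm = ln,
       cell_type = typing$cell_type[counts$cells$cell_id],
       discarded_samples = bad_samples$discard,
       doublets = dbl$doublets, report = report)
}
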
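# ---------------------------------------------------------------------------
# Simplified reference-relative CNV inference from single-cell
# transcriptomes: per-gene log-ratios to a reference cell set, clipping,
# genomically ordered moving-average smoothing within chromosome, per-cell
# median centering; plus pseudo-bulk CNV clustering, arm-level summaries,
# marker-arm enrichment and marker-CNV concordance.  Deliberately without
# an HMM or subcluster denoising.
# ---------------------------------------------------------------------------

#' Infer a smoothed relative-expression CNV profile
#'
#' Genes with reference mean normalized expression below `min_ref_mean`
#' are dropped; per cell, the log(x+1)-scale ratio to the reference mean is
#' clipped to +/- `clip_sd` standard deviations, smoothed by a centered
#' moving average over `window` genomically ordered genes within each
#' chromosome (shrinking at chromosome edges), and median-centered per
#' cell.  Mitochondrial genes are excluded.
#'
#' @param lognorm an `sc_lognorm` whose gene table is a [gene_annotation()].
#' @param reference_cells cell ids of the reference (normal) set.
#' @param window moving-average width in genes (odd; default 101).
#' @param min_ref_mean reference-mean cutoff on normalized counts (0.1).
#' @param clip_sd clipping bound in sd units (default 3).
#' @return a `cnv_profile`: list with `scores` (cells x windows, one window
#'   per retained gene), `windows` (gene/chromosome/arm table) and
#'   `reference_cells`.
#' @export
infer_cnv_profile <- function(lognorm, reference_cells, window = 101L,
                              min_ref_mean = 0.1, clip_sd = 3) {
  stopifnot(inherits(lognorm, "sc_lognorm"))
  if (!length(reference_cells)) stop("reference cell set is empty")
  if (is.null(lognorm$genes$chromosome)) stop("genomic positions unavailable")
  ridx <- match(reference_cells, colnames(lognorm$data))
  if (anyNA(ridx)) stop("reference cell(s) absent from matrix")
  genes <- lognorm$genes
  ord <- order(match(genes$chromosome, unique(genes$chromosome)), genes$start_bp)
  keep_gene <- !genes$is_mito
  ref_mean_norm <- Matrix::rowMeans(expm1(lognorm$data[, ridx, drop = FALSE]))
  keep_gene <- keep_gene & ref_mean_norm >= min_ref_mean
  ord <- ord[keep_gene[ord]]
  X <- as.matrix(lognorm$data[ord, , drop = FALSE])
  ref <- rowMeans(X[, match(reference_cells, colnames(X)), drop = FALSE])
  R <- X - ref                                   # log(x+1)-space ratio
  s <- sd(R)
  R[R > clip_sd * s] <- clip_sd * s
  R[R < -clip_sd * s] <- -clip_sd * s
  chrom <- genes$chromosome[ord]
  for (ch in unique(chrom)) {
    ii <- which(chrom == ch)
    w <- min(window, length(ii))
    if (w %% 2L == 0L) w <- w - 1L
    if (w > 1L)
      R[ii, ] <- apply(R[ii, , drop = FALSE], 2, running_mean, w = w)
  }
  R <- sweep(R, 2, apply(R, 2, median), "-")     # per-cell median centering
  structure(list(scores = t(R),
                 windows = data.frame(gene_id = genes$gene_id[ord],
                                      chromosome = chrom,
                                      arm = arm_label(genes)[ord],
                                      start_bp = genes$start_bp[ord],
                                      stringsAsFactors = FALSE),
                 reference_cells = reference_cells,
                 window = window),
            class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat("cnv_profile:", nrow(x$scores), "entities x", ncol(x$scores),
      "gene windows (window", x$window, ")\n")
  invisible(x)
}

# entity x window matrix averaged into groups (patients etc.)
cnv_group_means <- function(profile, groups) {
  g <- if (!is.null(names(groups))) groups[rownames(profile$scores)] else groups
  ids <- sort(unique(g[!is.na(g)]))
  t(vapply(ids, function(i)
    colMeans(profile$scores[which(g == i), , drop = FALSE]),
    numeric(ncol(profile$scores))))
}

#' Cluster patients by pseudo-bulk CNV profiles
#'
#' Per-patient mean CNV profile, Ward hierarchical clustering cut at k = 2,
#' and the best label-matching concordance with transcriptome-derived
#' subtype labels.
#'
#' @param profile a `cnv_profile` over cells.
#' @param patients per-cell patient labels (named by cell id, or in row
#'   order of the profile).
#' @param transcriptome_labels named per-patient subtype labels to compare
#'   against (optional).
#' @return list with `groups` (per patient, 1/2), `concordance` (in [0,1],
#'   NA when no labels given), `tree` and the `pseudobulk` matrix.
#' @export
cluster_cnv_pseudobulk <- function(profile, patients,
                                   transcriptome_labels = NULL) {
  pb <- cnv_group_means(profile, patients)
  if (nrow(pb) < 4) stop("need >= 4 patients")
  if (all(dist(pb) < 1e-12)) stop("degenerate CNV profiles: no 2-group structure")
  tree <- hclust(dist(pb), method = "ward.D2")
  grp <- cutree(tree, k = 2)
  conc <- NA_real_
  if (!is.null(transcriptome_labels)) {
    common <- intersect(names(grp), names(transcriptome_labels))
    conc <- match_accuracy(grp[common], transcriptome_labels[common])
  }
  list(groups = grp, concordance = conc, tree = tree, pseudobulk = pb)
}

#' Arm-level CNV summary and gain/loss calls
#'
#' The arm score is the mean of window scores on the arm; an arm is called
#' "gain" above `+threshold`, "loss" below `-threshold`, else "neutral".
#' Arms with no profiled genes are neutral with a flag.
#'
#' @param profile a `cnv_profile`.
#' @param groups optional per-entity grouping; scores are averaged within
#'   groups before calling.
#' @param threshold call threshold (default 0.05).
#' @param all_arms optional arm universe to report (defaults to profiled
#'   arms).
#' @return list with `scores` (entities/groups x arms) and `calls`
#'   (same shape, "gain"/"loss"/"neutral").
#' @export
arm_level_summary <- function(profile, groups = NULL, threshold = 0.05,
                              all_arms = NULL) {
  M <- if (is.null(groups)) profile$scores else cnv_group_means(profile, groups)
  arms <- profile$windows$arm
  arm_ids <- all_arms %||% unique(arms)
  sc <- vapply(arm_ids, function(a) {
    ii <- which(arms == a)
    if (!length(ii)) return(rep(NA_real_, nrow(M)))
    rowMeans(M[, ii, drop = FALSE])
  }, numeric(nrow(M)))
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = nrow(M), dimnames = list(rownames(M), arm_ids))
  calls <- ifelse(is.na(sc), "neutral",
                  ifelse(sc > threshold, "gain",
                         ifelse(sc < -threshold, "loss", "neutral")))
  attr(calls, "unprofiled_arms") <- arm_ids[colSums(!is.na(sc)) == 0]
  list(scores = sc, calls = calls, threshold = threshold)
}

#' Marker enrichment in chromosomal arms
#'
#' Expressed genes are those with non-zero counts in at least
#' `min_expr_frac` of cells.  Per arm: expressed-gene count, marker count,
#' marker density (markers / expressed) and a hypergeometric enrichment
#' p-value, BH-adjusted across arms.
#'
#' @param marker_genes character vector of marker gene ids (e.g. the i2 or
#'   i3 set).
#' @param counts an [sc_counts()] (detection computed on counts).
#' @param min_expr_frac detection threshold (default 0.05).
#' @return data.frame per arm: `n_expressed`, `n_markers`, `density`, `p`,
#'   `q`.
#' @export
marker_arm_enrichment <- function(marker_genes, counts, min_expr_frac = 0.05) {
  stopifnot(inherits(counts, "sc_counts"))
  det <- Matrix::rowMeans(counts$counts > 0)
  expressed <- det >= min_expr_frac
  arms <- arm_label(counts$genes)
  is_marker <- counts$genes$gene_id %in% marker_genes
  m_tot <- sum(expressed & is_marker)
  n_tot <- sum(expressed & !is_marker)
  rows <- do.call(rbind, lapply(sort(unique(arms)), function(a) {
    on_arm <- arms == a
    k <- sum(expressed & on_arm)
    x <- sum(expressed & on_arm & is_marker)
    p <- if (k == 0) NA_real_ else phyper(x - 1, m_tot, n_tot, k, lower.tail = FALSE)
    data.frame(arm = a, n_expressed = k, n_markers = x,
               density = if (k > 0) x / k else NA_real_, p = p,
               stringsAsFactors = FALSE)
  }))
  rows$q <- p.adjust(rows$p, "BH")
  rows
}

#' Concordance between marker direction and arm-level CNV calls
#'
#' Restricted to signature genes on arms called gain or loss in i2: a gene
#' is concordant when its i2-relative direction matches the dosage
#' direction (up on a gained arm, down on a lost arm).  i3_Up counts as
#' down-in-i2 and i3_Down as up-in-i2.
#'
#' @param signature a [signature_set()] with classes i2 and i3.
#' @param arm_calls named character of arm -> "gain"/"loss"/"neutral" for
#'   the i2 group (e.g. one row of [arm_level_summary()] calls).
#' @param genes a [gene_annotation()] resolving marker positions.
#' @return list with `concordance` (fraction), `n_on_called_arms` and the
#'   per-gene `table`.
#' @export
marker_cnv_concordance <- function(signature, arm_calls, genes) {
  dir_i2 <- c(setNames(rep("up", length(signature$sets$i2$up)), signature$sets$i2$up),
              setNames(rep("down", length(signature$sets$i2$down)), signature$sets$i2$down),
              setNames(rep("down", length(signature$sets$i3$up)), signature$sets$i3$up),
              setNames(rep("up", length(signature$sets$i3$down)), signature$sets$i3$down))
  arm_of <- setNames(arm_label(genes), genes$gene_id)
  tab <- data.frame(gene_id = names(dir_i2),
                    direction_in_i2 = unname(dir_i2),
                    arm = arm_of[names(dir_i2)],
                    stringsAsFactors = FALSE)
  tab$arm_call <- arm_calls[tab$arm]
  tab <- tab[!is.na(tab$arm_call) & tab$arm_call != "neutral", ]
  if (!nrow(tab)) stop("no signature genes on gain/loss-called arms")
  tab$concordant <- (tab$direction_in_i2 == "up" & tab$arm_call == "gain") |
    (tab$direction_in_i2 == "down" & tab$arm_call == "loss")
  list(concordance = mean(tab$concordant), n_on_called_arms = nrow(tab),
       table = tab)
}
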
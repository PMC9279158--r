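# ---------------------------------------------------------------------------
# Discovery of the two intrinsic epithelial subtypes: feature selection,
# SNN/Louvain clustering, the pairwise-DEG feature-refinement recipe,
# normal-like cluster identification, the patient pseudo-bulk PCA split and
# the stage-one marker-consistency rule.
# ---------------------------------------------------------------------------

#' Differential-expression parameters for the Wilcoxon pairwise-DEG recipe
#'
#' Defaults follow the standard single-cell convention: natural-log
#' fold-change threshold 0.4055 (fold-change 1.5), min.pct 0.25, BH-adjusted
#' p < 0.05, a minimum average expression of 0.1 for the upregulated group,
#' and the union of the 30 most significant genes per direction per pair.
#'
#' @param logfc_threshold natural-log fold-change threshold (0.4055).
#' @param min_pct minimum detection fraction in the higher group (0.25).
#' @param adj_p_max BH-adjusted p-value ceiling (0.05).
#' @param min_up_group_mean minimum mean log-normalised expression in the
#'   upregulated group (0.1).
#' @param top_n_per_direction genes kept per direction per pair (30).
#' @return a `deg_params` list.
#' @export
deg_params <- function(logfc_threshold = 0.4055, min_pct = 0.25,
                       adj_p_max = 0.05, min_up_group_mean = 0.1,
                       top_n_per_direction = 30L) {
  stopifnot(logfc_threshold > 0, min_pct > 0, adj_p_max > 0,
            top_n_per_direction >= 1)
  structure(as.list(environment()), class = "deg_params")
}

#' Select clustering features
#'
#' Deterministic feature selection over genes expressed in at least
#' `min_cells_frac` of cells.  Method `"hvg"` ranks genes by log-expression
#' variance; `"correlation_range"` ranks genes by the strength of their
#' strongest absolute correlation with any other candidate gene (genes that
#' co-vary in modules score high, isolated noise genes score low).
#'
#' @param lognorm an `sc_lognorm`.
#' @param method "correlation_range" or "hvg".
#' @param n_features number of features to return (default 500).
#' @param min_cells_frac detection filter applied first (default 0.01).
#' @return character vector of gene ids, ranked best first.
#' @export
select_features <- function(lognorm, method = c("correlation_range", "hvg"),
                            n_features = 500L, min_cells_frac = 0.01) {
  stopifnot(inherits(lognorm, "sc_lognorm"))
  method <- match.arg(method)
  if (ncol(lognorm$data) < 2) stop("need >= 2 cells")
  det <- Matrix::rowMeans(lognorm$data > 0)
  cand <- which(det >= min_cells_frac & det > 0)
  if (length(cand) < 10) stop("fewer than 10 candidate features")
  X <- lognorm$data[cand, , drop = FALSE]
  score <- if (method == "hvg") {
    rowVars_sparse(X)
  } else {
    C <- cor(t(as.matrix(X)))
    diag(C) <- 0
    apply(abs(C), 1, max)
  }
  ord <- order(score, decreasing = TRUE,
               lognorm$genes$gene_id[cand])  # deterministic tie-break
  sel <- cand[ord][seq_len(min(n_features, length(cand)))]
  lognorm$genes$gene_id[sel]
}

#' Cluster cells on an SNN graph in PCA space
#'
#' Community detection (Louvain) on a shared-nearest-neighbour graph built
#' in PCA space of the feature submatrix; seeded and deterministic.
#'
#' @param lognorm an `sc_lognorm`.
#' @param features gene ids to use.
#' @param resolution Louvain resolution (default 0.2).
#' @param seed RNG seed.
#' @param n_pcs PCA dimensions (default 15).
#' @param k SNN neighbours (default 20).
#' @param scale z-scale genes before PCA (default TRUE).
#' @param cohorts optional per-cell cohort labels; when given, genes are
#'   z-scaled within each cohort before merging (batch-effect removal).
#' @return integer cluster vector named by cell id, with attributes
#'   `features` and `resolution`.
#' @export
cluster_cells <- function(lognorm, features, resolution = 0.2, seed = 1L,
                          n_pcs = 15L, k = 20L, scale = TRUE,
                          cohorts = NULL) {
  stopifnot(inherits(lognorm, "sc_lognorm"), length(features) > 0)
  if (ncol(lognorm$data) < 2) stop("cannot cluster a singleton dataset")
  idx <- match(features, lognorm$genes$gene_id)
  if (anyNA(idx)) stop("feature(s) absent from matrix")
  X <- as.matrix(lognorm$data[idx, , drop = FALSE])
  if (!is.null(cohorts)) X <- zscore_within_cohort(X, cohorts)
  else if (scale) X <- scale_rows(X)
  pc <- prcomp(t(X), center = !scale, scale. = FALSE,
               rank. = min(n_pcs, nrow(X) - 1L, ncol(X) - 1L))$x
  cl <- snn_louvain(pc, k = k, resolution = resolution, seed = seed)
  structure(setNames(cl, colnames(lognorm$data)),
            features = features, resolution = resolution)
}

# mean of expm1 per gene for a cell subset, plus detection fraction
group_stats <- function(X, idx) {
  sub <- X[, idx, drop = FALSE]
  list(mean_expm1 = Matrix::rowMeans(expm1(sub)),
       mean_log = Matrix::rowMeans(sub),
       pct = Matrix::rowMeans(sub > 0))
}

#' Pairwise differential expression between clusters
#'
#' For every cluster pair: Wilcoxon rank-sum p per gene, BH adjustment,
#' natural-log fold-change of mean de-logged expression, detection
#' fractions.  A gene is a DEG when adjusted p < `adj_p_max`,
#' |lnFC| >= `logfc_threshold`, max(pct) >= `min_pct` and the upregulated
#' group's mean log expression >= `min_up_group_mean`.  The refined feature
#' set is the union over pairs of the top `top_n_per_direction` genes per
#' direction by adjusted p (ties by |lnFC| descending, then gene id).
#'
#' @param lognorm an `sc_lognorm`.
#' @param clusters per-cell cluster labels (named by cell id, or in order).
#' @param params a [deg_params()].
#' @return list with `tables` (one data.frame per pair) and `features`
#'   (the refined union).
#' @export
pairwise_deg <- function(lognorm, clusters, params = deg_params()) {
  stopifnot(inherits(lognorm, "sc_lognorm"))
  cl <- if (!is.null(names(clusters))) clusters[colnames(lognorm$data)] else clusters
  ids <- sort(unique(cl))
  if (length(ids) < 2) stop("need >= 2 clusters")
  if (any(table(cl) == 0)) stop("empty cluster")
  X <- lognorm$data
  genes <- lognorm$genes$gene_id
  tables <- list()
  feats <- character()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    a <- which(cl == ids[i]); b <- which(cl == ids[j])
    sa <- group_stats(X, a); sb <- group_stats(X, b)
    lfc <- log((sa$mean_expm1 + 1e-9) / (sb$mean_expm1 + 1e-9))
    p <- row_wilcoxon(X, a, b)
    padj <- p.adjust(p, "BH")
    up_mean <- ifelse(lfc > 0, sa$mean_log, sb$mean_log)
    deg <- padj < params$adj_p_max &
      abs(lfc) >= params$logfc_threshold &
      pmax(sa$pct, sb$pct) >= params$min_pct &
      up_mean >= params$min_up_group_mean
    tab <- data.frame(gene_id = genes, lnfc = lfc, p = p, p_adj = padj,
                      pct_1 = sa$pct, pct_2 = sb$pct, is_deg = deg,
                      stringsAsFactors = FALSE)
    key <- paste0(ids[i], "_vs_", ids[j])
    tables[[key]] <- tab
    for (dir in c(1, -1)) {
      cand <- which(deg & sign(lfc) == dir)
      ord <- cand[order(padj[cand], -abs(lfc[cand]), genes[cand])]
      feats <- c(feats, genes[head(ord, params$top_n_per_direction)])
    }
  }
  list(tables = tables, features = sort(unique(feats)))
}

#' Identify normal-like epithelial clusters
#'
#' A cluster is normal-like when it contains more than `frac_threshold` of
#' all normal-tissue epithelial cells, or its internal normal-cell fraction
#' exceeds the dataset-wide normal fraction by at least `enrich_factor`.
#' Tumor-sample cells in the remaining clusters are "malignant".
#'
#' @param clusters per-cell cluster labels (named by cell id, or in order
#'   of `cell_metadata`).
#' @param cell_metadata data.frame with `cell_id` and `tissue`.
#' @param frac_threshold see above (default 0.5).
#' @param enrich_factor see above (default 3).
#' @return list with `normal_like_clusters`, per-cell `is_normal_like` and
#'   `is_malignant` (logical, named by cell id).
#' @export
identify_normal_like <- function(clusters, cell_metadata,
                                 frac_threshold = 0.5, enrich_factor = 3) {
  cl <- if (!is.null(names(clusters))) clusters[cell_metadata$cell_id] else clusters
  is_norm <- cell_metadata$tissue == "normal"
  if (!any(is_norm)) {
    warning("no normal-tissue cells; returning empty normal-like set")
    return(list(normal_like_clusters = integer(),
                is_normal_like = setNames(rep(FALSE, length(cl)), cell_metadata$cell_id),
                is_malignant = setNames(cell_metadata$tissue == "tumor",
                                        cell_metadata$cell_id)))
  }
  base_frac <- mean(is_norm)
  nl <- vapply(sort(unique(cl)), function(g) {
    inc <- cl == g
    frac_of_normals <- sum(is_norm & inc) / sum(is_norm)
    own_frac <- mean(is_norm[inc])
    frac_of_normals > frac_threshold || own_frac >= enrich_factor * base_frac
  }, logical(1))
  nl_ids <- sort(unique(cl))[nl]
  is_nl <- cl %in% nl_ids
  list(normal_like_clusters = nl_ids,
       is_normal_like = setNames(is_nl, cell_metadata$cell_id),
       is_malignant = setNames(!is_nl & cell_metadata$tissue == "tumor",
                               cell_metadata$cell_id))
}

#' Split patients into two groups by pseudo-bulk PCA
#'
#' Patient pseudo-bulk = per-patient mean of log-normalised malignant cells
#' over the supplied feature genes; genes are zero-centered and scaled to
#' unit variance, PCA is applied, and the patients are split by 2-means on
#' the first two principal components (seeded).  Group labels are
#' deterministic: "g1" is the group containing the alphabetically first
#' patient.
#'
#' @param lognorm an `sc_lognorm`.
#' @param malignant_cells cell ids of malignant epithelial cells.
#' @param deg_features feature gene ids.
#' @param seed RNG seed for 2-means.
#' @param min_cells patients with fewer malignant cells are excluded with a
#'   warning (default 20).
#' @return list with `groups` (named "g1"/"g2" character vector by patient),
#'   `pca` (patient x PC coordinates), `pseudobulk` (patients x genes).
#' @export
patient_pseudobulk_split <- function(lognorm, malignant_cells, deg_features,
                                     seed = 1L, min_cells = 20L) {
  stopifnot(inherits(lognorm, "sc_lognorm"))
  idx <- match(malignant_cells, colnames(lognorm$data))
  if (anyNA(idx)) stop("malignant cell(s) absent from matrix")
  pat <- lognorm$cells$patient_id[idx]
  sizes <- table(pat)
  small <- names(sizes)[sizes < min_cells]
  if (length(small)) {
    warning("excluding patient(s) with < ", min_cells, " malignant cells: ",
            paste(small, collapse = ", "))
    keep <- !pat %in% small
    idx <- idx[keep]; pat <- pat[keep]
  }
  pats <- sort(unique(pat))
  if (length(pats) < 4) stop("need >= 4 patients for the pseudo-bulk split")
  gi <- match(deg_features, lognorm$genes$gene_id)
  if (anyNA(gi)) stop("feature(s) absent from matrix")
  pb <- t(vapply(pats, function(p)
    Matrix::rowMeans(lognorm$data[gi, idx[pat == p], drop = FALSE]),
    numeric(length(gi))))
  colnames(pb) <- deg_features
  z <- t(scale_rows(t(pb)))   # zero-center / unit-variance each gene
  pc <- prcomp(z, center = FALSE, rank. = min(10L, length(pats) - 1L))$x
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  km <- kmeans(pc[, 1:2, drop = FALSE], centers = 2, nstart = 25)
  if (!is.null(old)) assign(".Random.seed", envir = globalenv(), value = old)
  g <- km$cluster
  if (g[[1]] != 1) g <- 3L - g  # pats is sorted: g1 holds the first patient
  groups <- setNames(paste0("g", g), pats)
  list(groups = groups, pca = pc, pseudobulk = pb)
}

#' Derive stage-one subtype markers from sample-origin pseudo-bulks
#'
#' Builds per (patient, tissue) pseudo-bulk transcriptomes for each of the
#' three epithelial classes, then runs the pairwise-DEG recipe between the
#' classes on those pseudo-bulk profiles.  A marker of a class is a gene
#' significantly upregulated relative to BOTH other classes.
#'
#' @param lognorm an `sc_lognorm`.
#' @param cell_class per-cell class labels: exactly three classes (the two
#'   tumor subtypes plus the normal-like class), NA to ignore; named by
#'   cell id.
#' @param params a [deg_params()].
#' @param min_cells minimum cells per (patient, tissue, class) pseudo-bulk.
#' @return a [signature_set()] with the three classes (Up sets only;
#'   markers are defined by upregulation).
#' @export
derive_stage1_markers <- function(lognorm, cell_class, params = deg_params(),
                                  min_cells = 10L) {
  stopifnot(inherits(lognorm, "sc_lognorm"))
  cls <- cell_class[colnames(lognorm$data)]
  use <- !is.na(cls)
  key <- paste(lognorm$cells$patient_id, lognorm$cells$tissue, cls, sep = "|")
  keys <- unique(key[use])
  keep_key <- keys[vapply(keys, function(k) sum(use & key == k) >= min_cells, logical(1))]
  pb <- vapply(keep_key, function(k)
    Matrix::rowMeans(lognorm$data[, use & key == k, drop = FALSE]),
    numeric(nrow(lognorm$data)))
  pb_class <- vapply(strsplit(keep_key, "|", fixed = TRUE), `[`, character(1), 3)
  pb_pat <- vapply(strsplit(keep_key, "|", fixed = TRUE), `[`, character(1), 1)
  classes <- sort(unique(pb_class))
  if (length(classes) != 3)
    stop("expected exactly 3 classes, got: ", paste(classes, collapse = ", "))
  for (cl in classes)
    if (length(unique(pb_pat[pb_class == cl])) < 2)
      stop("class ", cl, " has fewer than 2 patients")
  up_vs <- list()  # up_vs[[a]][[b]] = genes up in a vs b
  for (a in classes) for (b in classes) {
    if (a >= b) next
    ia <- which(pb_class == a); ib <- which(pb_class == b)
    sa <- list(mean_expm1 = rowMeans(expm1(pb[, ia, drop = FALSE])),
               mean_log = rowMeans(pb[, ia, drop = FALSE]),
               pct = rowMeans(pb[, ia, drop = FALSE] > 0))
    sb <- list(mean_expm1 = rowMeans(expm1(pb[, ib, drop = FALSE])),
               mean_log = rowMeans(pb[, ib, drop = FALSE]),
               pct = rowMeans(pb[, ib, drop = FALSE] > 0))
    lfc <- log((sa$mean_expm1 + 1e-9) / (sb$mean_expm1 + 1e-9))
    p <- row_wilcoxon(pb, ia, ib)
    padj <- p.adjust(p, "BH")
    up_mean <- ifelse(lfc > 0, sa$mean_log, sb$mean_log)
    deg <- padj < params$adj_p_max & abs(lfc) >= params$logfc_threshold &
      pmax(sa$pct, sb$pct) >= params$min_pct & up_mean >= params$min_up_group_mean
    g <- lognorm$genes$gene_id
    up_vs[[a]][[b]] <- g[deg & lfc > 0]
    up_vs[[b]][[a]] <- g[deg & lfc < 0]
  }
  sets <- lapply(setNames(classes, classes), function(a) {
    others <- setdiff(classes, a)
    list(up = intersect(up_vs[[a]][[others[1]]], up_vs[[a]][[others[2]]]),
         down = character())
  })
  signature_set(sets, provenance = "stage-one sample-origin pseudo-bulk markers")
}
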
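# ---------------------------------------------------------------------------
# Final signature derivation: summed pseudo-bulk counts, per-gene NB GLM
# with a cohort covariate (median-of-ratios size factors, ML dispersion with
# a moment fallback, Wald test), the directional consistency rule, and the
# DEG-count distance dendrogram.
# ---------------------------------------------------------------------------

#' Sum UMI counts into patient pseudo-bulk profiles
#'
#' @param counts an [sc_counts()].
#' @param groups per-cell aggregation labels (e.g. patient ids), named by
#'   cell id or in column order.
#' @param cells optional cell ids to restrict to (e.g. malignant cells).
#' @return samples x genes integer matrix (one row per group).
#' @export
sum_pseudobulk <- function(counts, groups, cells = NULL) {
  stopifnot(inherits(counts, "sc_counts"))
  g <- if (!is.null(names(groups))) groups[counts$cells$cell_id] else groups
  m <- counts$counts
  if (!is.null(cells)) {
    keep <- counts$cells$cell_id %in% cells
    m <- m[, keep, drop = FALSE]
    g <- g[keep]
  }
  if (any(is.na(g))) { m <- m[, !is.na(g), drop = FALSE]; g <- g[!is.na(g)] }
  ids <- sort(unique(g))
  if (!length(ids)) stop("no cells to aggregate")
  mm <- Matrix::sparseMatrix(i = seq_along(g), j = match(g, ids), x = 1,
                             dims = c(length(g), length(ids)))
  pb <- t(as.matrix(m %*% mm))      # groups x genes
  dimnames(pb) <- list(ids, rownames(m))
  storage.mode(pb) <- "integer"
  pb
}

#' Drop genes detected in too few individuals
#'
#' Genes with a non-zero pseudo-bulk count in fewer than `min_frac` of the
#' rows are discarded (strictly fewer; exactly at the fraction is kept).
#'
#' @param pb samples x genes pseudo-bulk count matrix.
#' @param min_frac detection fraction threshold (default 0.05).
#' @return filtered matrix.
#' @export
filter_detected <- function(pb, min_frac = 0.05) {
  det <- colMeans(pb > 0)
  pb[, det >= min_frac, drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Computed over genes with strictly positive counts in every sample
#' (positive geometric mean), as in the standard RNA-seq normalisation.
#'
#' @param pb samples x genes count matrix.
#' @return numeric size factors, one per row.
#' @export
size_factors <- function(pb) {
  lg <- log(t(pb))                          # genes x samples
  geo <- rowMeans(lg)
  use <- is.finite(geo)
  if (!any(use)) stop("no gene has positive counts in all samples")
  sf <- apply(exp(lg[use, , drop = FALSE] - geo[use]), 2, median)
  setNames(sf, rownames(pb))
}

# Per-gene NB GLM fit: ML dispersion (glm.nb) with a moment-based
# fallback.  The ML dispersion is biased low at pseudo-bulk sample sizes,
# so it is inflated by n/(n - p) and the Wald SE comes from a fixed-theta
# refit under the corrected dispersion.
fit_nb_gene <- function(y, design_df, sf, coef_name) {
  df <- cbind(y = y, design_df)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ . + offset(log(sf)), data = df,
                                  control = glm.control(maxit = 50))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    alpha <- 1 / fit$theta
  } else {
    # moment fallback: dispersion from Poisson residuals
    pfit <- tryCatch(suppressWarnings(
      glm(y ~ . + offset(log(sf)), data = df, family = poisson())),
      error = function(e) NULL)
    if (is.null(pfit)) return(c(NA, NA, NA, NA))
    mu <- fitted(pfit)
    alpha <- sum((y - mu)^2 - mu) / sum(mu^2)
  }
  p_par <- ncol(stats::model.matrix(~., design_df))
  alpha_adj <- max(alpha, 1e-8) * length(y) / (length(y) - p_par)
  fit <- tryCatch(suppressWarnings(
    glm(y ~ . + offset(log(sf)), data = df,
        family = MASS::negative.binomial(theta = 1 / alpha_adj))),
    error = function(e) NULL)
  if (is.null(fit)) return(c(NA, NA, NA, NA))
  sm <- summary(fit)$coefficients
  if (!coef_name %in% rownames(sm)) return(c(NA, NA, NA, NA))
  est <- sm[coef_name, 1]; se <- sm[coef_name, 2]
  c(est, se, length(y) - nrow(sm), as.numeric(isTRUE(fit$converged)))
}

#' Negative-binomial Wald test on pseudo-bulk counts
#'
#' Size factors by median-of-ratios; per-gene NB GLM with log link and
#' design `~ group + cohort` (the cohort covariate is dropped when only one
#' cohort is present); gene-wise dispersion by maximum likelihood with a
#' moment-based fallback; Wald test on the group coefficient against a t
#' reference with residual degrees of freedom (the ML dispersion estimate
#' is noisy at pseudo-bulk sample sizes, where a normal reference is
#' anticonservative); BH adjustment across converged genes.
#'
#' @param pb samples x genes pseudo-bulk count matrix.
#' @param group per-sample group labels (2 groups).
#' @param contrast character c(numerator, denominator); log2FC is
#'   numerator over denominator.
#' @param cohort optional per-sample cohort labels.
#' @return data.frame per gene: `log2fc`, `se`, `p`, `q`, `base_mean`
#'   (depth-normalised mean count), `converged`.
#' @export
nb_deg_test <- function(pb, group, contrast = NULL, cohort = NULL) {
  group <- as.character(group)
  lv <- unique(group)
  if (length(lv) != 2) stop("group must have exactly 2 levels")
  if (is.null(contrast)) contrast <- rev(lv)
  if (!all(sort(contrast) == sort(lv))) stop("contrast must name the 2 groups")
  if (min(table(group)) < 2) stop("need >= 2 samples per group")
  fac <- factor(group, levels = c(contrast[2], contrast[1]))
  design_df <- data.frame(grp = fac)
  if (!is.null(cohort) && length(unique(cohort)) > 1)
    design_df$cohort <- factor(cohort)
  sf <- size_factors(pb)
  base_mean <- colMeans(sweep(pb, 1, sf, "/"))
  coef_name <- paste0("grp", contrast[1])
  res <- t(apply(pb, 2, fit_nb_gene, design_df = design_df, sf = sf,
                 coef_name = coef_name))
  est <- res[, 1]; se <- res[, 2]; dfree <- res[, 3]
  converged <- res[, 4] == 1 & !is.na(est)
  p <- rep(NA_real_, ncol(pb))
  ok <- converged & is.finite(se) & se > 0
  p[ok] <- 2 * pt(-abs(est[ok] / se[ok]), df = pmax(dfree[ok], 1))
  q <- rep(NA_real_, ncol(pb))
  q[ok] <- p.adjust(p[ok], "BH")
  data.frame(gene_id = colnames(pb),
             log2fc = est / log(2), se = se / log(2),
             p = p, q = q, base_mean = base_mean,
             converged = converged,
             row.names = colnames(pb), stringsAsFactors = FALSE)
}

#' Signature thresholds for the final marker derivation
#'
#' @param log2fc_min absolute log2 fold-change floor (log2(1.5)).
#' @param q_max BH q-value ceiling (0.05).
#' @param abundance_mode "percentile": base mean must reach the
#'   `abundance_cut` quantile of tested genes; "absolute": base mean must
#'   reach `abundance_cut` directly.
#' @param abundance_cut see above (default 0.75).
#' @return a `signature_params` list.
#' @export
signature_params <- function(log2fc_min = log2(1.5), q_max = 0.05,
                             abundance_mode = c("percentile", "absolute"),
                             abundance_cut = 0.75) {
  structure(list(log2fc_min = log2fc_min, q_max = q_max,
                 abundance_mode = match.arg(abundance_mode),
                 abundance_cut = abundance_cut),
            class = "signature_params")
}

deg_pass <- function(res, params, base_mean = NULL) {
  bm <- if (is.null(base_mean)) res$base_mean else unname(base_mean[res$gene_id])
  cut <- if (params$abundance_mode == "percentile")
    quantile(bm, params$abundance_cut, na.rm = TRUE)
  else params$abundance_cut
  ok <- !is.na(res$q) & res$q <= params$q_max &
    abs(res$log2fc) >= params$log2fc_min & bm >= cut
  data.frame(gene_id = res$gene_id,
             up = ok & res$log2fc > 0,
             down = ok & res$log2fc < 0)
}

#' Derive the final directional iCMS signature
#'
#' From the three pairwise contrasts (i2 vs i3, i3 vs normal, normal vs
#' i2): a gene is `i2_Up` only when upregulated — passing every threshold —
#' against BOTH i3 and normal-like, `i2_Down` when down against both, and
#' likewise for i3.  The four direction sets are disjoint by construction.
#'
#' @param contrasts named list of [nb_deg_test()] results:
#'   `i2_vs_i3`, `i3_vs_normal`, `normal_vs_i2`.
#' @param params a [signature_params()].
#' @param base_mean optional named dataset-wide depth-normalised mean
#'   counts (over all pseudo-bulk samples); when supplied, the abundance
#'   cut is shared across the three contrasts instead of recomputed per
#'   contrast.
#' @return a [signature_set()] with classes `i2` and `i3`.
#' @export
derive_icms_signature <- function(contrasts, params = signature_params(),
                                  base_mean = NULL) {
  need <- c("i2_vs_i3", "i3_vs_normal", "normal_vs_i2")
  miss <- setdiff(need, names(contrasts))
  if (length(miss)) stop("missing contrast(s): ", paste(miss, collapse = ", "))
  a <- deg_pass(contrasts$i2_vs_i3, params, base_mean)      # i2 over i3
  b <- deg_pass(contrasts$i3_vs_normal, params, base_mean)  # i3 over normal
  c_ <- deg_pass(contrasts$normal_vs_i2, params, base_mean) # normal over i2
  g <- a$gene_id
  stopifnot(identical(g, b$gene_id), identical(g, c_$gene_id))
  i2_up <- g[a$up & c_$down]     # up vs i3 and up vs normal
  i2_dn <- g[a$down & c_$up]
  i3_up <- g[a$down & b$up]      # up vs i2 and up vs normal
  i3_dn <- g[a$up & b$down]
  signature_set(list(i2 = list(up = i2_up, down = i2_dn),
                     i3 = list(up = i3_up, down = i3_dn)),
                provenance = "pseudo-bulk NB consistency-rule signature")
}

#' DEG-count distance matrix and dendrogram between groups
#'
#' The pairwise distance between two groups is the number of genes passing
#' the signature thresholds in the NB test between them; the tree is built
#' by average-linkage hierarchical clustering on that matrix.
#'
#' @param pb samples x genes pseudo-bulk count matrix.
#' @param group per-sample group labels (>= 3 groups).
#' @param cohort optional per-sample cohort labels.
#' @param params a [signature_params()].
#' @return list with `dist` (symmetric matrix, zero diagonal) and `tree`
#'   (an `hclust`).
#' @export
deg_count_distance <- function(pb, group, cohort = NULL,
                               params = signature_params()) {
  ids <- sort(unique(as.character(group)))
  if (length(ids) < 3) stop("need >= 3 groups")
  sizes <- table(group)
  if (min(sizes) < 2) stop("group(s) with < 2 samples: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    sel <- group %in% c(ids[i], ids[j])
    res <- nb_deg_test(pb[sel, , drop = FALSE], group[sel],
                       contrast = c(ids[i], ids[j]),
                       cohort = if (!is.null(cohort)) cohort[sel])
    pass <- deg_pass(res, params)
    d[i, j] <- d[j, i] <- sum(pass$up | pass$down)
  }
  list(dist = d, tree = hclust(as.dist(d), method = "average"))
}
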
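# ---------------------------------------------------------------------------
# End-to-end driver reproducing the stage order of the original analysis:
# QC -> discovery (feature refinement, pseudo-bulk split, stage-one
# markers) -> merged-cohort subtyping -> CNV inference and concordance ->
# pseudo-bulk NB signature -> metagene scoring -> bulk NTP -> IMF.
# ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' @param seed master seed; every stochastic stage derives from it.
#' @param qc a [qc_thresholds()].
#' @param deg a [deg_params()].
#' @param sig a [signature_params()].
#' @param feature_method feature selection method for discovery.
#' @param n_features features selected for initial clustering.
#' @param resolution_initial,resolution_refined Louvain resolutions for the
#'   initial and refined clustering rounds (0.2 / 0.5).
#' @param score_delta metagene score-difference threshold (0.1).
#' @param n_perm NTP permutations.
#' @param ntp_q NTP indeterminate threshold (0.05).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            qc = qc_thresholds(),
                            deg = deg_params(),
                            sig = signature_params(),
                            feature_method = "correlation_range",
                            n_features = 500L,
                            resolution_initial = 0.2,
                            resolution_refined = 0.5,
                            score_delta = 0.1,
                            n_perm = 1000L,
                            ntp_q = 0.05) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full subtyping pipeline end to end
#'
#' @param sc an [sc_counts()] multi-cohort single-cell dataset.
#' @param reference_profiles genes x cell-type reference matrix for
#'   cell typing (log scale).
#' @param bulk optional [bulk_matrix()] to classify by NTP/IMF.
#' @param msi_labels optional named per-patient MSI labels
#'   ("MSI-H"/"MSS") for the DEG-count dendrogram.
#' @param fibroblast_markers optional fibroblast marker genes for the
#'   fibrosis metagene fallback on unlabeled bulk samples.
#' @param config a [pipeline_config()].
#' @return list of stage outputs plus a machine-readable `report`.
#' @export
run_end_to_end <- function(sc, reference_profiles, bulk = NULL,
                           msi_labels = NULL, fibroblast_markers = NULL,
                           config = pipeline_config()) {
  cfg <- config
  report <- list()

  ## ---- QC ---------------------------------------------------------------
  qc <- run_qc(sc, reference_profiles, cfg$qc, seed = cfg$seed)
  report$qc <- qc$report
  report$discarded_samples <- qc$discarded_samples

  epi_idx <- which(qc$cell_type == "epithelial")
  if (length(epi_idx) < 100) stop("stage qc: too few epithelial cells survive")
  epi <- sc_subset(qc$counts, cells = epi_idx)
  epi_ln <- lognormalize(epi)
  report$n_epithelial <- ncol(epi_ln$data)

  ## ---- discovery on the largest cohort ----------------------------------
  co_sizes <- table(epi_ln$cells$cohort_id)
  disc_co <- names(co_sizes)[which.max(co_sizes)]
  disc <- sc_subset(epi_ln, cells = which(epi_ln$cells$cohort_id == disc_co))
  feats <- select_features(disc, cfg$feature_method, n_features = cfg$n_features)
  cl0 <- cluster_cells(disc, feats, resolution = cfg$resolution_initial,
                       seed = cfg$seed)
  pw <- pairwise_deg(disc, cl0, cfg$deg)
  if (length(pw$features) < 10) stop("stage discovery: refined feature set too small")
  report$discovery_cohort <- disc_co
  report$n_initial_clusters <- length(unique(cl0))

  ## ---- merged subtyping on refined features (per-cohort z-scaled) --------
  # if the graph is too coarse for the normal-like rule to isolate the
  # normal branch (few malignant patients survive), refine the resolution
  pat_of <- setNames(epi_ln$cells$patient_id, epi_ln$cells$cell_id)
  res_m <- cfg$resolution_refined
  repeat {
    clm <- cluster_cells(epi_ln, pw$features, resolution = res_m,
                         seed = cfg$seed, cohorts = epi_ln$cells$cohort_id)
    nlm <- identify_normal_like(clm, epi_ln$cells)
    malignant <- names(nlm$is_malignant)[nlm$is_malignant]
    enough <- sum(table(pat_of[malignant]) >= 20) >= 4
    if (enough || res_m >= 4 * cfg$resolution_refined) break
    res_m <- res_m * 2
  }
  report$n_refined_clusters <- length(unique(clm))
  report$n_malignant <- length(malignant)

  # patient pseudo-bulk PCA split across all cohorts (batch-corrected)
  epi_z <- epi_ln
  epi_z$data <- zscore_within_cohort(epi_ln$data, epi_ln$cells$cohort_id)
  rownames(epi_z$data) <- epi_ln$genes$gene_id
  split <- patient_pseudobulk_split(epi_z, malignant, pw$features,
                                    seed = cfg$seed)
  report$discovery_groups <- split$groups

  # stage-one markers from sample-origin pseudo-bulks (classes g1/g2/normal)
  cls <- rep(NA_character_, ncol(epi_ln$data))
  names(cls) <- colnames(epi_ln$data)
  cls[nlm$is_normal_like[colnames(epi_ln$data)]] <- "normal"
  cls[epi_ln$cells$tissue == "normal"] <- "normal"
  cls[malignant] <- unname(split$groups[pat_of[malignant]])
  stage1 <- derive_stage1_markers(epi_ln, cls, cfg$deg)
  report$stage1_sizes <- vapply(stage1$sets, function(s) length(s$up), integer(1))

  # cells follow their patient's split group (re-examined per cell at the
  # final metagene-scoring stage)
  g_names <- setdiff(names(stage1$sets), "normal")
  patient_group <- split$groups
  cell_group <- unname(patient_group[pat_of[malignant]])
  names(cell_group) <- malignant

  ## ---- CNV inference -----------------------------------------------------
  normal_like <- names(nlm$is_normal_like)[nlm$is_normal_like]
  cnv <- infer_cnv_profile(epi_ln, reference_cells = normal_like)
  cnv_cl <- cluster_cnv_pseudobulk(
    sc_profile_subset(cnv, malignant), pat_of[malignant],
    transcriptome_labels = patient_group)
  report$cnv_concordance <- cnv_cl$concordance

  # orient group names: the aneuploid transcriptome group is iCMS2-like
  arm_by_group <- arm_level_summary(
    sc_profile_subset(cnv, malignant),
    groups = unname(patient_group[pat_of[malignant]]))
  burden <- rowMeans(abs(arm_by_group$scores), na.rm = TRUE)
  i2_name <- names(which.max(burden))
  relabel <- setNames(ifelse(g_names == i2_name, "i2", "i3"), g_names)
  patient_subtype <- unname(relabel[patient_group])
  names(patient_subtype) <- names(patient_group)
  cell_subtype <- unname(relabel[cell_group])
  names(cell_subtype) <- names(cell_group)
  report$patient_subtype <- patient_subtype

  # consistent patients: CNV grouping agrees with transcriptome grouping
  cg <- cnv_cl$groups
  maps <- list(c(`1` = "i2", `2` = "i3"), c(`1` = "i3", `2` = "i2"))
  agree <- vapply(maps, function(m)
    mean(m[as.character(cg)] == patient_subtype[names(cg)]), numeric(1))
  cnv_subtype <- maps[[which.max(agree)]][as.character(cg)]
  consistent <- names(cg)[cnv_subtype == patient_subtype[names(cg)]]
  report$n_consistent_patients <- length(consistent)

  ## ---- pseudo-bulk NB signature ------------------------------------------
  mal_use <- malignant[pat_of[malignant] %in% consistent]
  pb_mal <- sum_pseudobulk(epi, pat_of, cells = mal_use)
  pb_norm <- sum_pseudobulk(epi, pat_of, cells = normal_like)
  rownames(pb_norm) <- paste0(rownames(pb_norm), "_normal")
  pb <- rbind(pb_mal, pb_norm)
  pb <- filter_detected(pb)
  grp <- c(unname(patient_subtype[rownames(pb_mal)]),
           rep("normal", nrow(pb_norm)))
  coh_of <- setNames(epi_ln$cells$cohort_id,  epi_ln$cells$patient_id)
  coh <- unname(coh_of[sub("_normal$", "", rownames(pb))])
  contrasts <- list()
  for (cn in list(c("i2", "i3"), c("i3", "normal"), c("normal", "i2"))) {
    sel <- grp %in% cn
    contrasts[[paste0(cn[1], "_vs_", cn[2])]] <-
      nb_deg_test(pb[sel, , drop = FALSE], grp[sel], contrast = cn,
                  cohort = coh[sel])
  }
  bm_global <- setNames(colMeans(sweep(pb, 1, size_factors(pb), "/")),
                        colnames(pb))
  signature <- derive_icms_signature(contrasts, cfg$sig, base_mean = bm_global)
  empty <- vapply(signature$sets, function(s) length(s$up) + length(s$down) == 0,
                  logical(1))
  if (any(empty))
    stop("stage signature: no genes pass the thresholds for class ",
         paste(names(empty)[empty], collapse = ", "),
         " (too few patients per group?)")
  report$signature_sizes <- c(
    i2_Up = length(signature$sets$i2$up), i2_Down = length(signature$sets$i2$down),
    i3_Up = length(signature$sets$i3$up), i3_Down = length(signature$sets$i3$down))

  ## ---- metagene scoring / cell classification ----------------------------
  sig_genes <- intersect(signature_genes(signature), epi_ln$genes$gene_id)
  zs <- zscore_within_cohort(epi_ln$data[match(sig_genes, epi_ln$genes$gene_id), ,
                                         drop = FALSE],
                             epi_ln$cells$cohort_id)
  rownames(zs) <- sig_genes
  s_i2 <- metagene_score(zs, signature$sets$i2$up)
  s_i3 <- metagene_score(zs, signature$sets$i3$up)
  scoring <- classify_cells_by_score(
    s_i2[malignant], s_i3[malignant], delta = cfg$score_delta,
    tumor = unname(pat_of[malignant]))
  final_cell_subtype <- ifelse(s_i2[malignant] > s_i3[malignant], "i2", "i3")
  names(final_cell_subtype) <- malignant
  report$frac_preferential <- mean(scoring$call != "ambiguous")
  report$n_hybrid_tumors <- sum(scoring$composition$hybrid)
  report$bimodality_components <- scoring$bimodality$n_components

  ## ---- arm summaries and marker-CNV concordance --------------------------
  arm_sub <- arm_level_summary(
    sc_profile_subset(cnv, malignant),
    groups = unname(final_cell_subtype))
  enrich <- list(
    i2 = marker_arm_enrichment(c(signature$sets$i2$up, signature$sets$i2$down), epi),
    i3 = marker_arm_enrichment(c(signature$sets$i3$up, signature$sets$i3$down), epi))
  conc <- tryCatch(
    marker_cnv_concordance(signature, arm_sub$calls["i2", ], epi_ln$genes),
    error = function(e) list(concordance = NA_real_, n_on_called_arms = 0L))
  report$marker_cnv_concordance <- conc$concordance

  ## ---- DEG-count dendrogram ----------------------------------------------
  dendro <- NULL
  if (!is.null(msi_labels)) {
    gmsi <- paste0(patient_subtype[rownames(pb_mal)],
                   ifelse(msi_labels[rownames(pb_mal)] == "MSI-H", "_MSI", "_MSS"))
    keep_g <- names(table(gmsi))[table(gmsi) >= 2]
    if (length(keep_g) >= 3) {
      sel <- gmsi %in% keep_g
      dendro <- deg_count_distance(pb_mal[sel, , drop = FALSE], gmsi[sel],
                                   cohort = coh_of[rownames(pb_mal)][sel],
                                   params = cfg$sig)
      report$dendrogram_merge <- dendro$tree$merge
    }
  }

  ## ---- bulk classification -----------------------------------------------
  ntp <- imf <- fib <- NULL
  if (!is.null(bulk)) {
    bz <- zscore_within_cohort(bulk$expr, bulk$samples$cohort_id)
    ntp <- ntp_classify(bz, signature, n_perm = cfg$n_perm,
                        q_threshold = cfg$ntp_q, seed = cfg$seed)
    fib <- fibrosis_flag(bulk, fibroblast_markers = fibroblast_markers)
    imf <- imf_classify(ntp, setNames(bulk$samples$msi, bulk$samples$sample_id), fib)
    report$ntp_fractions <- prop.table(table(ntp$prediction))
    report$imf_fractions <- prop.table(table(imf$class))
  }

  list(qc = qc, stage1 = stage1, signature = signature,
       discovery = list(features = feats, refined = pw$features,
                        split = split, normal_like = nlm, clusters = clm),
       cell_subtype = final_cell_subtype, patient_subtype = patient_subtype,
       scores = list(i2 = s_i2, i3 = s_i3), scoring = scoring,
       cnv = cnv, cnv_clustering = cnv_cl, arm_summary = arm_sub,
       marker_arm_enrichment = enrich, marker_cnv_concordance = conc,
       dendrogram = dendro, ntp = ntp, fibrosis = fib, imf = imf,
       contrasts = contrasts, report = report)
}

# subset a cnv_profile to a set of entities
sc_profile_subset <- function(profile, entities) {
  profile$scores <- profile$scores[intersect(entities, rownames(profile$scores)), ,
                                   drop = FALSE]
  profile
}
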
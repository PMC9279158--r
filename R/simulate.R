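# ---------------------------------------------------------------------------
# Synthetic multi-cohort single-cell + bulk generator with full ground truth.
# The generator is a pure function of (config, seed): negative-binomial UMI
# counts over cell-type base profiles, planted subtype marker shifts,
# arm-level dosage effects, patient/cohort random effects, doublets,
# degraded samples and a normal-like epithelial admixture in tumors.
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is validated under:
#' five cohorts of four patients, two planted intrinsic subtypes with
#' natural-log fold-change ln(2) marker shifts, arm dosage 1.5x (gains) and
#' 0.5x (losses) confined to the i2 subtype, a 23.4% normal-like epithelial
#' admixture in tumor samples, doublets at 0.8% per 1,000 recovered cells,
#' and MSI-H status restricted to i3 patients.
#'
#' @param n_cohorts number of single-cell cohorts.
#' @param patients_per_cohort patients per cohort (one tumor sample each).
#' @param cells_per_sample cells per tumor sample (doublets included).
#' @param normal_cells_per_sample cells per adjacent-normal sample.
#' @param normal_sample_frac fraction of patients with a paired normal sample.
#' @param n_genes total genes, including `n_mito_genes` mitochondrial genes.
#' @param cell_types names of the major cell types (default the 11 used for
#'   annotation: B, endothelial, entericglial, epithelial, fibroblast, mast,
#'   McDC, neutrophil, pDC, plasmaB, TNK).
#' @param tumor_props,normal_props named cell-type proportions per tissue.
#' @param subtype_fractions named fractions of patients per subtype
#'   (`i2`, `i3`); must sum to 1.
#' @param marker_counts planted directional marker counts, named
#'   `i2_Up`, `i2_Down`, `i3_Up`, `i3_Down`.
#' @param marker_lfc natural-log fold-change of planted markers (ln(2)).
#' @param msi_frac_in_i3 fraction of i3 patients labelled MSI-H (i2 patients
#'   are never MSI-H).
#' @param msi_marker_count,msi_marker_lfc planted MSI-specific expression
#'   program (genes shifted in MSI-H malignant cells only).
#' @param cnv_arms list per subtype: named numeric of arm -> dosage
#'   multiplier (e.g. `c("8q" = 1.5, "17p" = 0.5)`); applied multiplicatively
#'   to non-marker genes on the arm in malignant cells of that subtype.
#' @param marker_cnv_frac fraction of i2 markers placed on i2 dosage arms.
#' @param marker_cnv_concordant_frac of those, fraction placed concordantly
#'   (Up on gained arms / Down on lost arms).
#' @param nb_dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param library_size_meanlog,library_size_sdlog lognormal UMI depth.
#' @param doublet_rate_per_1000 doublet percentage per 1,000 recovered cells
#'   (10x linear rule); per-sample count = n * (rate * n/1000) / 100.
#' @param doublet_frac if non-NULL, overrides the linear rule with a fixed
#'   per-sample doublet fraction.
#' @param doublet_homotypic_frac fraction of doublets drawn from the same
#'   cell type (undetectable by pANN, hence kept configurable).
#' @param low_quality_sample_frac fraction of tumor samples degraded.
#' @param degraded_nodg_factor NODG retention factor in degraded samples
#'   (strictly below 0.5 so the factor-2 sample-QC rule can fire).
#' @param degraded_celltype_frac fraction of cell types affected in a
#'   degraded sample (default 8 of 11).
#' @param low_quality_cell_frac,low_quality_depth_factor,low_quality_mito_frac
#'   per-cell low-quality model: depth shrunk, mitochondrial fraction raised.
#' @param normal_like_frac_in_tumor fraction of tumor-sample epithelial
#'   cells that are normal-like rather than malignant (0.234).
#' @param patient_effect_sd,cohort_effect_sd per-gene lognormal random
#'   effects (patient identity; cohort batch shifts that per-cohort
#'   z-scaling must remove).
#' @param hybrid_tumor_frac fraction of patients whose tumor mixes both
#'   subtypes; `hybrid_minor_frac` is the minor-subtype cell fraction.
#' @param hybrid_minor_frac see above.
#' @param mito_frac baseline mitochondrial fraction of UMIs; `n_mito_genes`
#'   mitochondrial genes carry it.
#' @param n_mito_genes number of mitochondrial genes.
#' @param celltype_marker_count,celltype_marker_fc per-type identity genes
#'   and their fold elevation (drives reference-correlation typing).
#' @param marker_base_rate_mult planted markers draw their baseline
#'   expression around this multiple of the median gene (markers are
#'   well-expressed genes, as required for their detection).
#' @param n_bulk_samples,bulk_purity_shape1,bulk_purity_shape2 bulk cohort
#'   size and Beta parameters of tumor purity.
#' @param fibrotic_frac fraction of fibrotic (CMS4-like) bulk tumors.
#' @param fibroblast_weight_base,fibroblast_weight_fibrotic mean fibroblast
#'   mixture weight for non-fibrotic / fibrotic samples.
#' @param bulk_noise_sd Gaussian noise sd on log bulk expression.
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cohorts = 5L,
                       patients_per_cohort = 4L,
                       cells_per_sample = 800L,
                       normal_cells_per_sample = 500L,
                       normal_sample_frac = 0.5,
                       n_genes = 2000L,
                       cell_types = c("B", "endothelial", "entericglial",
                                      "epithelial", "fibroblast", "mast",
                                      "McDC", "neutrophil", "pDC", "plasmaB",
                                      "TNK"),
                       tumor_props = NULL,
                       normal_props = NULL,
                       subtype_fractions = c(i2 = 0.6, i3 = 0.4),
                       marker_counts = c(i2_Up = 60L, i2_Down = 50L,
                                         i3_Up = 40L, i3_Down = 30L),
                       marker_lfc = log(2),
                       msi_frac_in_i3 = 0.4,
                       msi_marker_count = 15L,
                       msi_marker_lfc = log(1.6),
                       cnv_arms = list(
                         i2 = c("8q" = 1.5, "13q" = 1.5, "20p" = 1.5,
                                "20q" = 1.5, "8p" = 0.5, "17p" = 0.5,
                                "18q" = 0.5),
                         i3 = c()),
                       marker_cnv_frac = 0.5,
                       marker_cnv_concordant_frac = 0.9,
                       nb_dispersion = 0.5,
                       library_size_meanlog = log(7000),
                       library_size_sdlog = 0.25,
                       doublet_rate_per_1000 = 0.8,
                       doublet_frac = NULL,
                       doublet_homotypic_frac = 0.3,
                       low_quality_sample_frac = 0.1,
                       degraded_nodg_factor = 0.45,
                       degraded_celltype_frac = 8 / 11,
                       low_quality_cell_frac = 0.05,
                       low_quality_depth_factor = 0.25,
                       low_quality_mito_frac = 0.3,
                       normal_like_frac_in_tumor = 0.234,
                       patient_effect_sd = 0.12,
                       cohort_effect_sd = 0.2,
                       hybrid_tumor_frac = 0,
                       hybrid_minor_frac = 0.5,
                       mito_frac = 0.08,
                       n_mito_genes = 13L,
                       celltype_marker_count = 60L,
                       celltype_marker_fc = 6,
                       marker_base_rate_mult = 8,
                       n_bulk_samples = 200L,
                       bulk_purity_shape1 = 6,
                       bulk_purity_shape2 = 3,
                       fibrotic_frac = 0.25,
                       fibroblast_weight_base = 0.08,
                       fibroblast_weight_fibrotic = 0.35,
                       bulk_noise_sd = 0.1,
                       seed = 1L) {
  if (is.null(tumor_props)) {
    tumor_props <- c(B = 0.05, endothelial = 0.05, entericglial = 0.02,
                     epithelial = 0.50, fibroblast = 0.08, mast = 0.02,
                     McDC = 0.06, neutrophil = 0.03, pDC = 0.02,
                     plasmaB = 0.04, TNK = 0.13)
  }
  if (is.null(normal_props)) {
    normal_props <- c(B = 0.04, endothelial = 0.04, entericglial = 0.02,
                      epithelial = 0.62, fibroblast = 0.06, mast = 0.02,
                      McDC = 0.04, neutrophil = 0.02, pDC = 0.01,
                      plasmaB = 0.03, TNK = 0.10)
  }
  cfg <- as.list(environment())
  cfg$tumor_props <- tumor_props / sum(tumor_props)
  cfg$normal_props <- normal_props / sum(normal_props)
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot(abs(sum(cfg$subtype_fractions) - 1) < 1e-8)
  fr <- c(cfg$normal_like_frac_in_tumor, cfg$low_quality_sample_frac,
          cfg$low_quality_cell_frac, cfg$hybrid_tumor_frac,
          cfg$marker_cnv_frac, cfg$marker_cnv_concordant_frac,
          cfg$msi_frac_in_i3, cfg$fibrotic_frac)
  if (any(fr < 0 | fr > 1)) stop("sim_config fractions must lie in [0, 1]")
  for (st in names(cfg$cnv_arms))
    if (length(cfg$cnv_arms[[st]]) && any(cfg$cnv_arms[[st]] <= 0))
      stop("dosage multipliers must be > 0")
  if (length(cfg$cell_types) != length(cfg$tumor_props))
    stop("tumor_props must cover every cell type")
  cfg
}

# Fixed chromosome-arm layout of the simulated genome.
sim_arm_layout <- function() {
  arms <- c("1p", "1q", "2p", "2q", "3p", "3q", "4q", "5p", "5q", "6p",
            "7p", "7q", "8p", "8q", "13q", "17p", "17q", "18q", "20p", "20q")
  data.frame(arm = arms,
             chromosome = sub("[pq]$", "", arms),
             arm_pq = substring(arms, nchar(arms)),
             stringsAsFactors = FALSE)
}

#' Build the simulated gene universe
#'
#' Partitions genes across chromosome arms with sorted positions, plants the
#' disjoint directional marker sets (optionally arm-resident with a
#' configured concordant fraction), the MSI program, per-cell-type identity
#' genes and mitochondrial genes, and draws baseline expression rates.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `genes` ([gene_annotation()]), `gene_truth` data.frame
#'   (marker class/direction, MSI membership, dosage arm effects),
#'   `base_rate`, `celltype_markers`, and `profiles` (genes x profile matrix
#'   of normalized expression rates, including malignant epithelial
#'   variants).
#' @export
build_gene_universe <- function(config, seed = config$seed) {
  cfg <- config
  set.seed(seed)
  layout <- sim_arm_layout()
  n_mt <- cfg$n_mito_genes
  n_nuc <- cfg$n_genes - n_mt
  if (n_nuc < sum(cfg$marker_counts) + cfg$msi_marker_count +
      length(cfg$cell_types) * cfg$celltype_marker_count)
    stop("over-allocation of markers: n_genes too small")
  per_arm <- rep(n_nuc %/% nrow(layout), nrow(layout))
  per_arm[seq_len(n_nuc %% nrow(layout))] <- per_arm[seq_len(n_nuc %% nrow(layout))] + 1L
  arm_of <- rep(layout$arm, per_arm)
  ids <- sprintf("g%04d", seq_len(n_nuc))
  genes <- data.frame(gene_id = ids,
                      symbol = ids,
                      chromosome = rep(layout$chromosome, per_arm),
                      arm = rep(layout$arm_pq, per_arm),
                      stringsAsFactors = FALSE)
  # positions increase along each chromosome, p arm before q
  genes$start_bp <- as.integer(ave(seq_len(n_nuc), genes$chromosome,
                                   FUN = seq_along) * 1e6L)
  genes$is_mito <- FALSE
  mito <- data.frame(gene_id = sprintf("mt%02d", seq_len(n_mt)),
                     symbol = sprintf("MT-%02d", seq_len(n_mt)),
                     chromosome = "MT", arm = "q",
                     start_bp = as.integer(seq_len(n_mt) * 1000L),
                     is_mito = TRUE, stringsAsFactors = FALSE)
  genes <- gene_annotation(rbind(genes, mito))

  # ---- marker placement -------------------------------------------------
  gain_arms <- function(st) names(cfg$cnv_arms[[st]])[cfg$cnv_arms[[st]] > 1]
  loss_arms <- function(st) names(cfg$cnv_arms[[st]])[cfg$cnv_arms[[st]] < 1]
  cnv_arm_names <- unique(unlist(lapply(cfg$cnv_arms, names)))
  neutral_arms <- setdiff(layout$arm, cnv_arm_names)
  pool <- split(ids, arm_of)
  used <- character()
  take <- function(arms, n) {
    avail <- setdiff(unlist(pool[arms], use.names = FALSE), used)
    if (n > length(avail)) stop("over-allocation of markers on arms ",
                                paste(arms, collapse = ","))
    g <- if (n > 0) sample(avail, n) else character()
    used <<- c(used, g)
    g
  }
  marker_class <- setNames(rep("none", nrow(genes)), genes$gene_id)
  marker_dir <- setNames(rep("none", nrow(genes)), genes$gene_id)
  for (nm in names(cfg$marker_counts)) {
    parts <- strsplit(nm, "_")[[1]]
    st <- parts[1]; dir <- parts[2]
    ntot <- cfg$marker_counts[[nm]]
    conc_arms <- if (dir == "Up") gain_arms(st) else loss_arms(st)
    disc_arms <- if (dir == "Up") loss_arms(st) else gain_arms(st)
    n_arm <- if (length(c(conc_arms, disc_arms)))
      round(cfg$marker_cnv_frac * ntot) else 0L
    n_conc <- if (length(conc_arms)) round(cfg$marker_cnv_concordant_frac * n_arm) else 0L
    n_disc <- if (length(disc_arms)) n_arm - n_conc else 0L
    g <- c(take(conc_arms, n_conc), take(disc_arms, n_disc),
           take(neutral_arms, ntot - n_conc - n_disc))
    marker_class[g] <- st
    marker_dir[g] <- dir
  }
  msi_genes <- take(neutral_arms, cfg$msi_marker_count)
  ct_markers <- lapply(setNames(cfg$cell_types, cfg$cell_types), function(t)
    take(layout$arm, cfg$celltype_marker_count))

  # ---- baseline rates and profiles --------------------------------------
  base <- setNames(rlnorm(n_nuc, meanlog = 0, sdlog = 1.2), ids)
  # subtype/MSI markers are well-expressed genes: baseline drawn around
  # marker_base_rate_mult times the median gene with a tight spread
  is_marker <- marker_class[ids] != "none" | ids %in% msi_genes
  base[is_marker] <- rlnorm(sum(is_marker),
                            meanlog = log(cfg$marker_base_rate_mult),
                            sdlog = 0.3)
  mito_w <- rlnorm(n_mt, 0, 0.3)

  make_profile <- function(mult) {
    r <- base * mult
    mt <- mito_w / sum(mito_w) * sum(r) * cfg$mito_frac / (1 - cfg$mito_frac)
    p <- c(r, mt)
    names(p) <- genes$gene_id
    p / sum(p)
  }
  profiles <- sapply(cfg$cell_types, function(t) {
    mult <- rep(1, n_nuc); names(mult) <- ids
    mult[ct_markers[[t]]] <- cfg$celltype_marker_fc
    make_profile(mult)
  })

  malig_mult <- function(st, msi = FALSE) {
    mult <- rep(1, n_nuc); names(mult) <- ids
    mult[ct_markers[["epithelial"]]] <- cfg$celltype_marker_fc
    dos <- cfg$cnv_arms[[st]]
    if (length(dos)) {
      on_arm <- arm_of %in% names(dos)
      mult[on_arm] <- mult[on_arm] * dos[arm_of[on_arm]]
    }
    # markers override dosage: the planted shift is the whole effect
    # (dosage acts multiplicatively on non-marker arm genes only)
    own <- marker_class[ids] == st
    up <- own & marker_dir[ids] == "Up"
    dn <- own & marker_dir[ids] == "Down"
    mult[up] <- exp(cfg$marker_lfc)
    mult[dn] <- exp(-cfg$marker_lfc)
    other <- c("i2", "i3")[c("i2", "i3") != st]
    mult[marker_class[ids] == other] <- 1  # other subtype's markers at baseline
    if (msi) mult[ids %in% msi_genes] <- mult[ids %in% msi_genes] * exp(cfg$msi_marker_lfc)
    mult
  }
  profiles <- cbind(profiles,
                    epithelial_i2 = make_profile(malig_mult("i2")),
                    epithelial_i3 = make_profile(malig_mult("i3")),
                    epithelial_i3_msi = make_profile(malig_mult("i3", msi = TRUE)))

  gene_truth <- data.frame(gene_id = genes$gene_id,
                           arm = arm_label(genes),
                           marker_class = marker_class[genes$gene_id],
                           marker_dir = marker_dir[genes$gene_id],
                           is_msi_marker = genes$gene_id %in% msi_genes,
                           stringsAsFactors = FALSE)
  for (st in c("i2", "i3")) {
    eff <- rep(1, nrow(genes))
    dos <- cfg$cnv_arms[[st]]
    if (length(dos)) {
      hit <- gene_truth$arm %in% names(dos)
      eff[hit] <- dos[gene_truth$arm[hit]]
    }
    gene_truth[[paste0("cnv_effect_", st)]] <- eff
  }
  list(genes = genes, gene_truth = gene_truth, base_rate = base,
       celltype_markers = ct_markers, profiles = profiles)
}

# patient table: subtype/MSI/fibrosis/hybrid assignments, deterministic in
# the seeded RNG stream.
sim_patients <- function(cfg) {
  n <- cfg$n_cohorts * cfg$patients_per_cohort
  ids <- sprintf("P%02d", seq_len(n))
  cohorts <- rep(sprintf("cohort%d", seq_len(cfg$n_cohorts)),
                 each = cfg$patients_per_cohort)
  n_i2 <- round(cfg$subtype_fractions[["i2"]] * n)
  # interleave so every cohort carries both subtypes
  subtype <- rep("i3", n)
  subtype[order(rep(seq_len(cfg$patients_per_cohort), cfg$n_cohorts))[seq_len(n_i2)]] <- "i2"
  i3_idx <- which(subtype == "i3")
  msi <- rep("MSS", n)
  n_msi <- round(cfg$msi_frac_in_i3 * length(i3_idx))
  if (n_msi > 0) msi[sample(i3_idx, n_msi)] <- "MSI-H"
  hybrid <- rep(FALSE, n)
  n_hyb <- round(cfg$hybrid_tumor_frac * n)
  if (n_hyb > 0) hybrid[sample(n, n_hyb)] <- TRUE
  fibrotic <- rep(FALSE, n)
  n_fib <- round(cfg$fibrotic_frac * n)
  if (n_fib > 0) fibrotic[sample(n, n_fib)] <- TRUE
  data.frame(patient_id = ids, cohort_id = cohorts, subtype = subtype,
             msi = msi, hybrid = hybrid, fibrotic = fibrotic,
             stringsAsFactors = FALSE)
}

#' Simulate multi-cohort single-cell data with ground truth
#'
#' @param config a [sim_config()].
#' @return list with `data` (an [sc_counts()] whose cell table carries the
#'   truth columns `true_cell_type`, `true_subtype`, `is_doublet`,
#'   `is_low_quality`), `truth` (per-sample, per-patient and per-gene truth
#'   plus the reference cell-type profiles used by the generator), and
#'   `universe`.
#' @export
simulate_sc_cohorts <- function(config) {
  cfg <- validate_sim_config(config)
  universe <- build_gene_universe(cfg, cfg$seed)
  set.seed(cfg$seed + 1L)
  genes <- universe$genes
  ng <- nrow(genes)
  P <- universe$profiles
  is_mt <- genes$is_mito
  patients <- sim_patients(cfg)

  # sample table
  samples <- do.call(rbind, lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    has_n <- (i %% round(1 / max(cfg$normal_sample_frac, 1e-9))) == 0
    rbind(data.frame(sample_id = paste0(p$patient_id, "_T"),
                     patient_id = p$patient_id, cohort_id = p$cohort_id,
                     tissue = "tumor", stringsAsFactors = FALSE),
          if (cfg$normal_sample_frac > 0 && has_n)
            data.frame(sample_id = paste0(p$patient_id, "_N"),
                       patient_id = p$patient_id, cohort_id = p$cohort_id,
                       tissue = "normal", stringsAsFactors = FALSE))
  }))
  tum <- which(samples$tissue == "tumor")
  n_deg <- round(cfg$low_quality_sample_frac * length(tum))
  samples$is_degraded <- FALSE
  if (n_deg > 0) samples$is_degraded[sample(tum, n_deg)] <- TRUE

  cohort_eff <- sapply(sprintf("cohort%d", seq_len(cfg$n_cohorts)), function(i)
    exp(rnorm(ng, 0, cfg$cohort_effect_sd)))
  patient_eff <- sapply(patients$patient_id, function(i)
    exp(rnorm(ng, 0, cfg$patient_effect_sd)))
  rownames(cohort_eff) <- rownames(patient_eff) <- genes$gene_id

  n_aff <- round(cfg$degraded_celltype_frac * length(cfg$cell_types))
  blocks <- vector("list", nrow(samples))
  meta <- vector("list", nrow(samples))
  for (si in seq_len(nrow(samples))) {
    sm <- samples[si, ]
    pat <- patients[match(sm$patient_id, patients$patient_id), ]
    n <- if (sm$tissue == "tumor") cfg$cells_per_sample else cfg$normal_cells_per_sample
    props <- if (sm$tissue == "tumor") cfg$tumor_props else cfg$normal_props
    type <- sample(names(props), n, replace = TRUE, prob = props)
    subtype <- rep(NA_character_, n)
    epi <- type == "epithelial"
    if (sm$tissue == "tumor") {
      norm_like <- epi & runif(n) < cfg$normal_like_frac_in_tumor
      subtype[norm_like] <- "normal"
      mal <- epi & !norm_like
      st <- rep(pat$subtype, n)
      if (pat$hybrid) {
        flip <- runif(n) < cfg$hybrid_minor_frac
        st[flip] <- c(i2 = "i3", i3 = "i2")[st[flip]]
      }
      subtype[mal] <- st[mal]
    } else subtype[epi] <- "normal"

    prof_name <- type
    msi_flag <- pat$msi == "MSI-H"
    prof_name[!is.na(subtype) & subtype == "i2"] <- "epithelial_i2"
    prof_name[!is.na(subtype) & subtype == "i3"] <-
      if (msi_flag) "epithelial_i3_msi" else "epithelial_i3"

    lowq <- runif(n) < cfg$low_quality_cell_frac
    depth <- rlnorm(n, cfg$library_size_meanlog, cfg$library_size_sdlog)
    depth[lowq] <- depth[lowq] * cfg$low_quality_depth_factor

    Ps <- P * (cohort_eff[, sm$cohort_id] * patient_eff[, sm$patient_id])
    Ps <- sweep(Ps, 2, colSums(Ps), "/")
    # low-quality cells: mitochondrial fraction raised
    Ps_lq <- Ps
    Ps_lq[is_mt, ] <- sweep(Ps_lq[is_mt, , drop = FALSE], 2,
                            colSums(Ps_lq[is_mt, , drop = FALSE]), "/") *
      cfg$low_quality_mito_frac
    Ps_lq[!is_mt, ] <- sweep(Ps_lq[!is_mt, , drop = FALSE], 2,
                             colSums(Ps_lq[!is_mt, , drop = FALSE]), "/") *
      (1 - cfg$low_quality_mito_frac)

    mu <- matrix(0, ng, n)
    for (j in seq_len(n)) {
      src <- if (lowq[j]) Ps_lq else Ps
      mu[, j] <- src[, prof_name[j]] * depth[j]
    }
    cnt <- matrix(rnbinom(ng * n, mu = mu, size = 1 / cfg$nb_dispersion), ng, n)

    # doublets: averaged-then-resampled pairs at the configured rate
    n_dbl <- if (!is.null(cfg$doublet_frac)) round(cfg$doublet_frac * n)
             else round(n * (cfg$doublet_rate_per_1000 * n / 1000) / 100)
    is_dbl <- rep(FALSE, n)
    if (n_dbl > 0) {
      slots <- sample(n, n_dbl)
      is_dbl[slots] <- TRUE
      for (j in slots) {
        homo <- runif(1) < cfg$doublet_homotypic_frac
        cand <- setdiff(if (homo) which(type == type[j]) else which(type != type[j]),
                        c(j, slots))
        if (!length(cand)) cand <- setdiff(seq_len(n), j)
        a <- j; b <- if (length(cand) == 1) cand else sample(cand, 1)
        tot <- cnt[, a] + cnt[, b]
        d <- round(0.75 * sum(tot))
        if (sum(tot) > 0)
          cnt[, j] <- rmultinom(1, d, tot / sum(tot))[, 1]
      }
    }

    # degraded sample: NODG cut to the configured factor in affected types
    if (isTRUE(sm$is_degraded)) {
      aff_types <- cfg$cell_types[seq_len(n_aff)]
      for (j in which(type %in% aff_types)) {
        det <- which(cnt[, j] > 0)
        det_mt <- det[is_mt[det]]
        det_nm <- det[!is_mt[det]]
        keep_nm <- max(0L, round(cfg$degraded_nodg_factor * length(det)) - length(det_mt))
        drop <- if (keep_nm < length(det_nm))
          sample(det_nm, length(det_nm) - keep_nm) else integer()
        cnt[drop, j] <- 0
      }
    }

    cid <- sprintf("%s_c%04d", sm$sample_id, seq_len(n))
    blocks[[si]] <- as(Matrix::Matrix(cnt, sparse = TRUE), "generalMatrix")
    meta[[si]] <- data.frame(cell_id = cid, sample_id = sm$sample_id,
                             patient_id = sm$patient_id,
                             cohort_id = sm$cohort_id, tissue = sm$tissue,
                             true_cell_type = type, true_subtype = subtype,
                             is_doublet = is_dbl, is_low_quality = lowq,
                             stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, blocks)
  cells <- do.call(rbind, meta)
  dat <- sc_counts(counts, cells, genes)
  reference <- log1p(1e4 * universe$profiles[, cfg$cell_types])
  list(data = dat,
       truth = list(patients = patients, samples = samples,
                    gene_truth = universe$gene_truth,
                    reference_profiles = reference,
                    profiles = universe$profiles),
       universe = universe, config = cfg)
}

#' Simulate a bulk transcriptome cohort as cell-type mixtures
#'
#' Each sample is the log of a convex mixture of cell-type mean expression
#' profiles (the epithelial component drawn from the sample's planted
#' subtype, with the MSI program when MSI-H) plus Gaussian noise.  Fibrotic
#' samples get an elevated fibroblast weight; MSI-H labels occur only among
#' i3 tumors.
#'
#' @param config a [sim_config()].
#' @param profiles optional genes x profile matrix of normalized rates (as
#'   produced by [build_gene_universe()]); rebuilt from `config` when NULL.
#' @param seed seed (defaults to `config$seed`); profile construction always
#'   uses `config$seed` so bulk and single-cell runs share one gene universe.
#' @return list with `data` (a [bulk_matrix()] carrying `msi`/`cms` labels)
#'   and `truth` (per-sample subtype, purity and mixture weights, plus the
#'   per-gene truth table).
#' @export
simulate_bulk_cohort <- function(config, profiles = NULL, seed = config$seed) {
  cfg <- validate_sim_config(config)
  universe <- build_gene_universe(cfg, cfg$seed)
  if (is.null(profiles)) profiles <- universe$profiles
  set.seed(seed + 2L)
  nb <- cfg$n_bulk_samples
  subtype <- sample(c("i2", "i3"), nb, replace = TRUE,
                    prob = cfg$subtype_fractions[c("i2", "i3")])
  msi <- ifelse(subtype == "i3" & runif(nb) < cfg$msi_frac_in_i3, "MSI-H", "MSS")
  fibrotic <- runif(nb) < cfg$fibrotic_frac
  purity <- stats::rbeta(nb, cfg$bulk_purity_shape1, cfg$bulk_purity_shape2)
  purity <- pmax(purity, 0.05)
  fibw <- pmax(rnorm(nb, ifelse(fibrotic, cfg$fibroblast_weight_fibrotic,
                                cfg$fibroblast_weight_base), 0.03), 0.01)
  other_types <- setdiff(cfg$cell_types, c("epithelial", "fibroblast"))
  expr <- matrix(0, nrow(profiles), nb,
                 dimnames = list(rownames(profiles),
                                 sprintf("bulk%03d", seq_len(nb))))
  weights <- matrix(0, nb, length(cfg$cell_types),
                    dimnames = list(colnames(expr), cfg$cell_types))
  for (j in seq_len(nb)) {
    fw <- min(fibw[j], (1 - purity[j]) * 0.9)
    rest <- 1 - purity[j] - fw
    ow <- runif(length(other_types)) + 0.1
    ow <- ow / sum(ow) * rest
    epi_prof <- if (subtype[j] == "i2") "epithelial_i2"
                else if (msi[j] == "MSI-H") "epithelial_i3_msi"
                else "epithelial_i3"
    w <- setNames(numeric(length(cfg$cell_types)), cfg$cell_types)
    w["epithelial"] <- purity[j]; w["fibroblast"] <- fw
    w[other_types] <- ow
    mix <- profiles[, epi_prof] * purity[j] + profiles[, "fibroblast"] * fw +
      profiles[, other_types, drop = FALSE] %*% ow
    if (abs(sum(w) - 1) > 1e-8) stop("mixture weights do not sum to 1")
    expr[, j] <- log1p(1e4 * mix) + rnorm(nrow(profiles), 0, cfg$bulk_noise_sd)
    weights[j, ] <- w
  }
  cms <- ifelse(fibrotic, "CMS4",
                ifelse(subtype == "i2", "CMS2",
                       ifelse(msi == "MSI-H", "CMS1", "CMS3")))
  sdf <- data.frame(sample_id = colnames(expr), msi = msi, cms = cms,
                    cohort_id = "bulkA", stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = colnames(expr), true_subtype = subtype,
                      msi = msi, fibrotic = fibrotic, purity = purity,
                      fibroblast_weight = weights[, "fibroblast"],
                      stringsAsFactors = FALSE)
  list(data = bulk_matrix(expr, sdf),
       truth = list(samples = truth, gene_truth = universe$gene_truth,
                    weights = weights),
       universe = universe, config = cfg)
}
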
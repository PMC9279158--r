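# QC stages: boundary behaviour is strict/lenient exactly as specified,
# and planted artefacts are recovered from generator truth.

test_that("empty-droplet filter discards strictly below the NODG threshold", {
  # cell j detects j*100 genes
  ng <- 1000
  m <- sapply(1:10, function(j) c(rep(1L, j * 100), rep(0L, ng - j * 100)))
  x <- toy_counts(m)
  kept <- filter_empty_droplets(x, min_nodg = 300)
  expect_equal(ncol(kept$counts), 8)          # 299 would go; 300 stays
  expect_equal(unname(nodg(kept)[1]), 300)
  expect_equal(ncol(filter_empty_droplets(x, 301)$counts), 7)
})

test_that("log-normalisation matches its closed form and normalisation identity", {
  m <- matrix(0L, 3, 2)
  m[1, 1] <- 20L; m[2, 1] <- 19980L; m[1, 2] <- 5L; m[3, 2] <- 5L
  x <- toy_counts(m)
  ln <- lognormalize(x, scale_factor = 1e4)
  expect_equal(ln$data[1, 1], log(11), tolerance = 1e-12)
  # all-zero gene stays zero; per-cell sum of expm1 equals the scale factor
  expect_true(all(ln$data[3, 1] == 0))
  expect_equal(unname(Matrix::colSums(expm1(ln$data))), c(1e4, 1e4),
               tolerance = 1e-9)
  m[, 1] <- 0L
  expect_error(lognormalize(toy_counts(m)), "zero total")
})

test_that("reference-correlation typing is exact on reference copies and on mixtures", {
  sim <- sim_small()
  ref <- sim$truth$reference_profiles
  # cells that ARE reference columns correlate 1.0 and type perfectly
  keep <- !sim$data$cells$is_doublet & !sim$data$cells$is_low_quality
  sub <- sc_subset(sim$data, cells = which(keep)[1:400])
  ln <- lognormalize(sub)
  fake <- ln
  fake$data <- Matrix::Matrix(ref[, rep(1:6, each = 40)][ln$genes$gene_id, ],
                              sparse = TRUE)
  colnames(fake$data) <- colnames(ln$data)[1:240]
  fake$cells <- ln$cells[1:240, ]
  res <- assign_major_cell_types(fake, ref, seed = 3)
  expect_true(all(res$max_correlation > 0.999))
  expect_gte(mean(res$cell_type == rep(colnames(ref)[1:6], each = 40)), 0.95)

  # constant cell vector -> unassigned
  fake$data[, 1] <- 1
  res2 <- assign_major_cell_types(fake, ref, seed = 3)
  expect_identical(unname(res2$cell_type[1]), "unassigned")
})

test_that("typing recovers planted cell types on simulated mixtures", {
  sim <- sim_small()
  keep <- !sim$data$cells$is_doublet & !sim$data$cells$is_low_quality
  sub <- sc_subset(sim$data, cells = which(keep))
  res <- assign_major_cell_types(lognormalize(sub),
                                 sim$truth$reference_profiles, seed = 3)
  expect_gte(mean(res$cell_type == sub$cells$true_cell_type), 0.93)
})

test_that("median-of-medians sample QC applies the strict factor-2, more-than-half rule", {
  # 11 cell types x 8 samples with fully controlled NODG medians
  types <- paste0("t", sprintf("%02d", 1:11))
  ng <- 1200
  build_sample <- function(sid, nodg_by_type) {
    m <- do.call(cbind, lapply(seq_along(types), function(ti)
      sapply(rep(nodg_by_type[ti], 5), function(k) c(rep(1L, k), rep(0L, ng - k)))))
    toy_counts(m, sample_id = rep(sid, ncol(m)))
  }
  base <- rep(800L, 11)
  samples <- lapply(sprintf("s%d", 1:8), build_sample, nodg_by_type = base)
  # s8: exactly half NODG (ratio exactly 2.0) in ALL types -> never flags
  samples[[8]] <- build_sample("s8", rep(400L, 11))
  # s7: beyond factor 2 in 6 of 11 types -> flagged
  dev <- base; dev[1:6] <- 300L
  samples[[7]] <- build_sample("s7", dev)
  counts <- samples[[1]]
  for (i in 2:8) {
    counts$counts <- cbind(counts$counts, samples[[i]]$counts)
    samples[[i]]$cells$cell_id <- paste0(samples[[i]]$cells$sample_id, "_",
                                         samples[[i]]$cells$cell_id)
    counts$cells <- rbind(counts$cells, samples[[i]]$cells)
  }
  colnames(counts$counts) <- counts$cells$cell_id
  rownames(counts$cells) <- counts$cells$cell_id
  ct <- setNames(rep(types, each = 5, times = 8), counts$cells$cell_id)
  res <- flag_low_quality_samples(counts, ct, qc_thresholds())
  expect_identical(res$discard, "s7")
  # 5 of 11 deviations is not "more than half"
  dev5 <- base; dev5[1:5] <- 300L
  samples5 <- build_sample("s6", dev5)
  counts$counts[, counts$cells$sample_id == "s6"] <- samples5$counts
  res5 <- flag_low_quality_samples(counts, ct, qc_thresholds())
  expect_false("s6" %in% res5$discard)
})

test_that("sample QC flags exactly the planted degraded samples", {
  sim <- sim_small()
  x <- filter_empty_droplets(sim$data)
  ct <- setNames(x$cells$true_cell_type, x$cells$cell_id)
  res <- flag_low_quality_samples(x, ct)
  planted <- sim$truth$samples$sample_id[sim$truth$samples$is_degraded]
  expect_setequal(res$discard, planted)
})

test_that("pANN doublet detection follows the expected-count rule and finds planted doublets", {
  expect_equal(expected_doublet_count(5000, 0.8), 200)   # 4% of 5,000
  cfg <- sim_config(n_cohorts = 1, patients_per_cohort = 1,
                    cells_per_sample = 1000, normal_sample_frac = 0,
                    doublet_frac = 0.05, low_quality_cell_frac = 0,
                    low_quality_sample_frac = 0, seed = 77)
  sim <- simulate_sc_cohorts(cfg)
  ln <- lognormalize(sim$data)
  thr <- qc_thresholds(doublet_rate_per_1000 = 0.05 * 100 * 1000 / 1000)
  res <- detect_doublets(ln, thr, seed = 4)
  truth <- sim$data$cells$cell_id[sim$data$cells$is_doublet]
  expect_gte(mean(truth %in% res$doublets), 0.5)
  # rate zero removes nothing
  res0 <- detect_doublets(ln, qc_thresholds(doublet_rate_per_1000 = 0), seed = 4)
  expect_length(res0$doublets, 0)
})

test_that("cell-type cutoffs keep boundary values and remove low-quality cells", {
  # NODG 900 epithelial vs min 1000 -> out; mito exactly at cap -> kept
  ng <- 1500
  mk <- function(k, mito_counts) c(rep(1L, k), rep(0L, ng - 13 - k), mito_counts)
  mito <- c(rep(FALSE, ng - 13), rep(TRUE, 13))
  # cell1: epithelial NODG 900; cell2: epithelial NODG 1100, mito exactly 20%
  c1 <- mk(900, rep(0L, 13))
  c2 <- c(rep(4L, 1100), rep(0L, ng - 13 - 1100), c(rep(100L, 11), 0L, 0L))
  stopifnot(sum(c2[mito]) / sum(c2) == 0.2)
  x <- toy_counts(cbind(c1, c2), mito = mito)
  ct <- setNames(c("epithelial", "epithelial"), x$cells$cell_id)
  kept <- apply_celltype_cutoffs(x, ct)
  expect_identical(colnames(kept$counts), "c002")

  # planted low-quality cells mostly removed at the default table
  sim <- sim_small()
  x2 <- filter_empty_droplets(sim$data)
  ct2 <- setNames(x2$cells$true_cell_type, x2$cells$cell_id)
  kept2 <- apply_celltype_cutoffs(x2, ct2)
  lowq <- x2$cells$cell_id[x2$cells$is_low_quality]
  expect_gte(mean(!lowq %in% kept2$cells$cell_id), 0.9)
})

test_that("QC stages only remove cells and are idempotent", {
  sim <- sim_small()
  x <- filter_empty_droplets(sim$data)
  x2 <- filter_empty_droplets(x)
  expect_identical(colnames(x2$counts), colnames(x$counts))
  ct <- setNames(x$cells$true_cell_type, x$cells$cell_id)
  k1 <- apply_celltype_cutoffs(x, ct)
  k2 <- apply_celltype_cutoffs(k1, ct)
  expect_identical(colnames(k2$counts), colnames(k1$counts))
  # counts are never edited, only columns dropped
  expect_identical(as.matrix(k1$counts),
                   as.matrix(x$counts[, colnames(k1$counts)]))
})
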
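# Subtype discovery: feature selection, SNN/Louvain clustering, the
# pairwise-DEG refinement recipe, normal-like identification, the patient
# pseudo-bulk PCA split and stage-one markers.

test_that("feature selection is deterministic and excludes undetected genes", {
  epi <- epi_small()
  f1 <- select_features(epi, "hvg", n_features = 300)
  f2 <- select_features(epi, "hvg", n_features = 300)
  expect_identical(f1, f2)
  undet <- epi$genes$gene_id[Matrix::rowSums(epi$data > 0) == 0]
  expect_length(intersect(f1, undet), 0)
  # too few candidates errors
  tiny <- sc_subset(epi, genes = 1:5, cells = 1:50)
  expect_error(select_features(tiny, "hvg"), "fewer than 10")
})

test_that("planted subtype markers score in the top decile of features", {
  epi <- epi_small()
  mal <- sc_subset(epi, cells = which(epi$cells$true_subtype %in% c("i2", "i3")))
  gt <- sim_small()$truth$gene_truth
  planted <- gt$gene_id[gt$marker_class != "none"]
  for (method in c("correlation_range", "hvg")) {
    ranked <- select_features(mal, method, n_features = nrow(mal$data))
    pctile <- match(planted, ranked) / length(ranked)
    # the typical planted marker sits in the top decile of feature scores,
    # and markers are broadly confined to the top quartile
    expect_lte(median(pctile, na.rm = TRUE), 0.10)
    expect_gte(mean(pctile <= 0.25, na.rm = TRUE), 0.8)
  }
})

test_that("clustering separates blobs and is invariant to cell order", {
  set.seed(5)
  ng <- 60
  blob <- function(center, n) sapply(seq_len(n), function(i)
    log1p(pmax(rnorm(ng, center, 0.3), 0)))
  X <- cbind(blob(c(rep(4, 30), rep(0, 30)), 80),
             blob(c(rep(0, 30), rep(4, 30)), 80))
  x <- toy_counts(matrix(2L, ng, 160))
  ln <- lognormalize(x)
  ln$data <- Matrix::Matrix(X, sparse = TRUE, dimnames = dimnames(ln$data))
  cl <- cluster_cells(ln, ln$genes$gene_id, resolution = 0.2, seed = 2)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:80])), 1)

  perm <- sample(160)
  ln2 <- sc_subset(ln, cells = perm)
  cl2 <- cluster_cells(ln2, ln2$genes$gene_id, resolution = 0.2, seed = 2)
  expect_equal(adjusted_rand_index_test(cl[perm], cl2), 1)
})

test_that("epithelial clustering recovers the planted i2/i3/normal structure", {
  epi <- epi_small()
  feats <- select_features(epi, "hvg", n_features = 400)
  cl <- cluster_cells(epi, feats, resolution = 0.2, seed = 2,
                      cohorts = epi$cells$cohort_id)
  truth <- epi$cells$true_subtype
  expect_gte(length(unique(cl)), 3)
  expect_gte(adjusted_rand_index_test(cl, truth), 0.8)
})

test_that("pairwise DEG finds nothing between identical clusters and caps the union", {
  epi <- epi_small()
  norm <- sc_subset(epi, cells = which(epi$cells$true_subtype == "normal"))
  # split one homogeneous population arbitrarily in two
  fake <- setNames(rep(1:2, length.out = ncol(norm$data)), colnames(norm$data))
  pw <- pairwise_deg(norm, fake)
  expect_equal(sum(pw$tables[[1]]$is_deg), 0)
  expect_length(pw$features, 0)

  # three groups: union bounded by pairs x 60
  three <- setNames(rep(1:3, length.out = ncol(epi$data)), colnames(epi$data))
  pw3 <- pairwise_deg(epi, three)
  expect_lte(length(pw3$features), 3 * 60)
})

test_that("pairwise DEG top slots are occupied by planted markers", {
  epi <- epi_small()
  mal <- sc_subset(epi, cells = which(epi$cells$true_subtype %in% c("i2", "i3")))
  cl <- setNames(mal$cells$true_subtype, mal$cells$cell_id)
  pw <- pairwise_deg(mal, cl)
  gt <- sim_small()$truth$gene_truth
  planted_dir <- gt$gene_id[gt$marker_class != "none"]
  cnv_dir <- gt$gene_id[gt$cnv_effect_i2 != 1]
  # top slots belong to genes with a genuinely planted effect
  expect_gte(mean(pw$features %in% c(planted_dir, cnv_dir)), 0.9)
})

test_that("normal-like clusters are identified by the admixture rule", {
  # cluster 1 holds 100% of normal cells plus 23% of tumor cells
  md <- data.frame(cell_id = sprintf("c%03d", 1:300),
                   tissue = c(rep("normal", 100), rep("tumor", 200)))
  cl <- c(rep(1L, 100), rep(1L, 46), rep(2L, 154))
  names(cl) <- md$cell_id
  res <- identify_normal_like(cl, md)
  expect_identical(res$normal_like_clusters, 1L)
  expect_false(any(res$is_malignant[md$tissue == "normal"]))
  expect_true(all(res$is_malignant[cl == 2 & md$tissue == "tumor"]))
  # a cluster with zero normal cells is never normal-like
  expect_false(2L %in% res$normal_like_clusters)
  # no normal cells at all -> empty set with warning
  md2 <- md; md2$tissue <- "tumor"
  expect_warning(res2 <- identify_normal_like(cl, md2), "no normal")
  expect_length(res2$normal_like_clusters, 0)
})

test_that("normal-like recall is high on generator truth", {
  epi <- epi_small()
  feats <- select_features(epi, "hvg", n_features = 400)
  cl <- cluster_cells(epi, feats, resolution = 0.5, seed = 2,
                      cohorts = epi$cells$cohort_id)
  res <- identify_normal_like(cl, epi$cells)
  truth_norm <- epi$cells$true_subtype == "normal"
  expect_gte(mean(res$is_normal_like[truth_norm]), 0.95)
})

test_that("patient pseudo-bulk split matches planted subtypes exactly", {
  sim <- sim_disc()
  keep <- with(sim$data$cells,
               !is_doublet & !is_low_quality & true_cell_type == "epithelial")
  epi <- lognormalize(sc_subset(sim$data, cells = which(keep)))
  mal <- epi$cells$cell_id[epi$cells$true_subtype %in% c("i2", "i3")]
  feats <- select_features(epi, "hvg", n_features = 300)
  split <- patient_pseudobulk_split(epi, mal, feats, seed = 9)
  truth <- setNames(sim$truth$patients$subtype, sim$truth$patients$patient_id)
  expect_equal(match_accuracy_test(split$groups, truth[names(split$groups)]), 1)

  # invariance to patient (cell) ordering
  perm <- sample(ncol(epi$data))
  epi2 <- sc_subset(epi, cells = perm)
  split2 <- patient_pseudobulk_split(epi2, mal, feats, seed = 9)
  expect_identical(split$groups[sort(names(split$groups))],
                   split2$groups[sort(names(split2$groups))])

  # identical patients produce identical pseudo-bulk rows
  pb <- split$pseudobulk
  expect_equal(dist(pb[rep(1, 2), ])[1], 0)
})

test_that("stage-one markers obey the both-others consistency rule", {
  sim <- sim_disc()
  keep <- with(sim$data$cells,
               !is_doublet & !is_low_quality & true_cell_type == "epithelial")
  epi <- lognormalize(sc_subset(sim$data, cells = which(keep)))
  cls <- epi$cells$true_subtype
  names(cls) <- epi$cells$cell_id
  sig <- derive_stage1_markers(epi, cls)
  expect_setequal(names(sig$sets), c("i2", "i3", "normal"))
  expect_length(intersect(sig$sets$i2$up, sig$sets$i3$up), 0)

  gt <- sim$truth$gene_truth
  planted_i2 <- gt$gene_id[gt$marker_class == "i2" & gt$marker_dir == "Up"]
  expect_gte(mean(planted_i2 %in% sig$sets$i2$up), 0.9)
  # genes with no planted upward effect in i2 stay out
  null_genes <- gt$gene_id[gt$marker_class == "none" & gt$cnv_effect_i2 == 1 &
                             !gt$is_msi_marker]
  expect_lte(mean(sig$sets$i2$up %in% null_genes), 0.1)
  # i2_Down genes are up in normal vs i2 but NOT vs i3 -> excluded from normal_Up
  i2_down <- gt$gene_id[gt$marker_class == "i2" & gt$marker_dir == "Down"]
  expect_length(intersect(sig$sets$normal$up, i2_down), 0)
})
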
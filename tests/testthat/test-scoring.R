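# Metagene scoring: per-cohort scaling, set averages, score-difference
# classification with bimodality, marker-to-cell-type assignment, bulk
# cell-type metagenes.

test_that("per-cohort z-scaling removes planted cohort shifts", {
  set.seed(12)
  ng <- 50; n <- 120
  base <- matrix(rnorm(ng * n), ng, n,
                 dimnames = list(sprintf("g%02d", 1:ng), sprintf("c%03d", 1:n)))
  cohorts <- rep(c("A", "B"), each = 60)
  shifted <- base
  shifted[, cohorts == "B"] <- shifted[, cohorts == "B"] + 2  # batch shift
  z <- zscore_within_cohort(shifted, cohorts)
  for (co in c("A", "B")) {
    expect_lt(max(abs(rowMeans(z[, cohorts == co]))), 1e-9)
    expect_equal(unname(apply(z[, cohorts == co], 1, sd)), rep(1, ng),
                 tolerance = 1e-9)
  }
  # constant gene -> all zeros, flagged
  shifted[1, ] <- 7
  z2 <- zscore_within_cohort(shifted, cohorts)
  expect_true(all(z2[1, ] == 0))
  expect_true("g01" %in% attr(z2, "zero_variance")$A)
  expect_error(zscore_within_cohort(base, c(rep("A", 119), "B")), "single entity")
})

test_that("metagene scores average set genes and honour zero-centering", {
  set.seed(13)
  z <- matrix(rnorm(40 * 200), 40, 200,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("c%03d", 1:200)))
  z <- t(scale(t(z)))
  s1 <- metagene_score(z, "g01")
  expect_equal(as.numeric(s1), unname(z["g01", ]))
  s <- metagene_score(z, sprintf("g%02d", 1:10))
  expect_equal(mean(s), 0, tolerance = 1e-9)
  # absent genes are ignored but recorded in coverage
  s2 <- metagene_score(z, c(sprintf("g%02d", 1:10), "nope1", "nope2"))
  expect_equal(as.numeric(s2), as.numeric(s))
  expect_equal(attr(s2, "coverage"), 10 / 12)
  expect_error(metagene_score(z, c("nopeA", "nopeB")), "zero coverage")
})

test_that("a planted half-sd shift moves the metagene by about that much", {
  set.seed(14)
  ng <- 60; n <- 2000
  m <- matrix(rnorm(ng * n), ng, n,
              dimnames = list(sprintf("g%02d", 1:ng), sprintf("c%04d", 1:n)))
  hot <- 1:(n / 2)
  m[1:20, hot] <- m[1:20, hot] + 0.5
  z <- zscore_within_cohort(m)
  s <- metagene_score(z, sprintf("g%02d", 1:20))
  gap <- mean(s[hot]) - mean(s[-hot])
  expect_equal(gap, 0.5, tolerance = 0.05)
})

test_that("score-difference classification applies the strict 0.1 rule", {
  i2 <- c(a = 0.15, b = 0.10, c = 0.00, d = -0.2)
  i3 <- c(a = 0.00, b = 0.00, c = 0.00, d = 0.0)
  res <- classify_cells_by_score(i2, i3, delta = 0.1)
  expect_identical(unname(res$call),
                   c("preferential_i2", "ambiguous", "ambiguous",
                     "preferential_i3"))
  # labels invariant to a shared affine rescaling of both scores
  # (away from the exact decision boundary, where fp rounding rules)
  res2 <- classify_cells_by_score(3 * i2 + 1, 3 * i3 + 1, delta = 0.3)
  expect_identical(res2$call[c("a", "c", "d")], res$call[c("a", "c", "d")])
})

test_that("non-hybrid tumors are majority-preferential and bimodal; hybrids flagged", {
  sim <- sim_small()
  epi <- epi_small()
  gt <- sim$truth$gene_truth
  sig <- signature_set(list(
    i2 = list(up = gt$gene_id[gt$marker_class == "i2" & gt$marker_dir == "Up"]),
    i3 = list(up = gt$gene_id[gt$marker_class == "i3" & gt$marker_dir == "Up"])))
  mal <- which(epi$cells$true_subtype %in% c("i2", "i3"))
  z <- zscore_within_cohort(as.matrix(epi$data[, mal]),
                            epi$cells$cohort_id[mal])
  rownames(z) <- epi$genes$gene_id
  s2 <- metagene_score(z, sig$sets$i2$up)
  s3 <- metagene_score(z, sig$sets$i3$up)
  res <- classify_cells_by_score(s2, s3, delta = 0.1,
                                 tumor = epi$cells$patient_id[mal])
  expect_false(any(res$composition$hybrid))
  expect_true(all(pmax(res$composition$frac_i2, res$composition$frac_i3) >= 0.8))
  expect_identical(res$bimodality$n_components, 2L)

  # a synthetic 50/50 tumor is flagged hybrid
  half <- c(rep("i2", 500), rep("i3", 500))
  sh2 <- c(rnorm(500, 0.5, 0.1), rnorm(500, -0.5, 0.1))
  res_h <- classify_cells_by_score(sh2, -sh2, delta = 0.1,
                                   tumor = rep("T1", 1000))
  expect_true(res_h$composition$hybrid[1])
})

test_that("markers are assigned to cell types by pseudo-bulk argmax", {
  sim <- sim_small()
  keep <- with(sim$data$cells, !is_doublet & !is_low_quality)
  sub <- sc_subset(sim$data, cells = which(keep))
  ln <- lognormalize(sub)
  ct <- setNames(sub$cells$true_cell_type, sub$cells$cell_id)
  ctm <- sim$universe$celltype_markers
  marker_sets <- list(setA = c(ctm$epithelial[1:20], ctm$TNK[1:20]),
                      setB = c(ctm$fibroblast[1:20], ctm$B[1:20]))
  res <- assign_markers_to_celltypes(ln, ct, marker_sets)
  # output partitions the input (every present gene assigned exactly once)
  expect_setequal(res$assignment$gene_id, unlist(marker_sets))
  expect_equal(anyDuplicated(res$assignment$gene_id), 0)
  acc <- mean(res$assignment$cell_type ==
                rep(c("epithelial", "TNK", "fibroblast", "B"), each = 20))
  expect_gte(acc, 0.95)
  expect_setequal(res$epithelial_specific$setA,
                  intersect(marker_sets$setA, ctm$epithelial[1:20]))
})

test_that("bulk cell-type metagenes track the planted fibroblast weight", {
  cfg <- sim_config(n_bulk_samples = 120, fibrotic_frac = 0.5, seed = 17)
  bulk <- simulate_bulk_cohort(cfg)
  z <- zscore_within_cohort(bulk$data$expr, bulk$data$samples$cohort_id)
  sets <- lapply(bulk$universe$celltype_markers, identity)
  sc <- bulk_celltype_metagenes(z, sets)
  expect_true(all(is.finite(sc)))
  w <- bulk$truth$samples$fibroblast_weight
  expect_gte(cor(w, sc[, "fibroblast"], method = "spearman"), 0.9)
  # a sample that is pure fibroblast profile scores highest for fibroblast
  pure <- log1p(1e4 * bulk$universe$profiles[, "fibroblast"])
  z2 <- zscore_within_cohort(cbind(bulk$data$expr, pure = pure),
                             rep("A", ncol(bulk$data$expr) + 1))
  sc2 <- bulk_celltype_metagenes(z2, sets)
  expect_identical(names(which.max(sc2["pure", ])), "fibroblast")
})
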
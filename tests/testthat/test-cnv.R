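# Reference-relative CNV inference: null behaviour, planted dosage
# detection, pseudo-bulk clustering concordance, arm summaries, enrichment
# and marker-CNV concordance.

cnv_fixture <- function() memo("cnv_fixture", {
  epi <- epi_small()
  ref <- epi$cells$cell_id[epi$cells$true_subtype == "normal"]
  list(epi = epi, ref = ref,
       profile = infer_cnv_profile(epi, reference_cells = ref))
})

test_that("a reference-identical query yields near-zero window scores", {
  fx <- cnv_fixture()
  epi <- fx$epi
  # split normal cells: half as reference, half as query
  norm <- which(epi$cells$true_subtype == "normal")
  ref <- epi$cells$cell_id[norm[seq(1, length(norm), by = 2)]]
  qry <- setdiff(epi$cells$cell_id[norm], ref)
  prof <- infer_cnv_profile(epi, reference_cells = ref)
  win_means <- colMeans(prof$scores[qry, , drop = FALSE])
  expect_lt(max(abs(win_means)), 0.05)
})

test_that("low-expression genes are dropped by the reference-mean cutoff", {
  fx <- cnv_fixture()
  epi <- fx$epi
  ref_mean <- Matrix::rowMeans(expm1(
    epi$data[, match(fx$ref, colnames(epi$data))]))
  low <- epi$genes$gene_id[ref_mean < 0.1 & !epi$genes$is_mito]
  expect_gt(length(low), 0)
  expect_length(intersect(low, fx$profile$windows$gene_id), 0)
  expect_false(any(epi$genes$gene_id[epi$genes$is_mito] %in%
                     fx$profile$windows$gene_id))
})

test_that("planted arm dosage lifts the subtype's arm scores above the null band", {
  fx <- cnv_fixture()
  epi <- fx$epi
  i2 <- epi$cells$cell_id[epi$cells$true_subtype == "i2"]
  arm <- arm_level_summary(fx$profile)
  i2_rows <- match(i2, rownames(arm$scores))
  cfg <- sim_small()$config
  gain_arms <- names(cfg$cnv_arms$i2)[cfg$cnv_arms$i2 > 1]
  neutral <- setdiff(colnames(arm$scores),
                     c(names(cfg$cnv_arms$i2), names(cfg$cnv_arms$i3)))
  null_band <- quantile(abs(arm$scores[i2_rows, neutral]), 0.975)
  for (a in intersect(gain_arms, colnames(arm$scores)))
    expect_gt(mean(arm$scores[i2_rows, a]), null_band)
})

test_that("CNV pseudo-bulk clustering recovers the planted dichotomy", {
  fx <- cnv_fixture()
  epi <- fx$epi
  mal <- epi$cells$cell_id[epi$cells$true_subtype %in% c("i2", "i3")]
  pat <- setNames(epi$cells$patient_id, epi$cells$cell_id)
  prof_mal <- fx$profile
  prof_mal$scores <- prof_mal$scores[mal, ]
  truth <- setNames(sim_small()$truth$patients$subtype,
                    sim_small()$truth$patients$patient_id)
  cl <- cluster_cnv_pseudobulk(prof_mal, pat[mal], truth)
  expect_gte(cl$concordance, 0.95)
  # concordance invariant to label swapping
  sw <- ifelse(truth == "i2", "i3", "i2"); names(sw) <- names(truth)
  cl2 <- cluster_cnv_pseudobulk(prof_mal, pat[mal], sw)
  expect_equal(cl$concordance, cl2$concordance)
  # degenerate all-equal profiles are rejected
  prof_flat <- prof_mal
  prof_flat$scores <- matrix(0, 6, ncol(prof_mal$scores),
                             dimnames = list(paste0("x", 1:6), NULL))
  expect_error(cluster_cnv_pseudobulk(prof_flat, setNames(paste0("P", 1:6),
                                                          paste0("x", 1:6))),
               "degenerate")
})

test_that("arm calls use the threshold and ignore window order within arm", {
  fx <- cnv_fixture()
  prof <- fx$profile
  flat <- prof
  flat$scores <- matrix(0, 4, ncol(prof$scores),
                        dimnames = list(paste0("e", 1:4), NULL))
  s <- arm_level_summary(flat)
  expect_true(all(s$calls == "neutral"))
  # permuting windows within each arm leaves arm calls unchanged
  perm <- unlist(lapply(split(seq_len(ncol(prof$scores)), prof$windows$arm),
                        sample), use.names = FALSE)
  prof_p <- prof
  prof_p$scores <- prof$scores[, perm]
  prof_p$windows <- prof$windows[perm, ]
  a1 <- arm_level_summary(prof)
  a2 <- arm_level_summary(prof_p)
  expect_identical(a1$calls[, sort(colnames(a1$calls))],
                   a2$calls[, sort(colnames(a2$calls))])
})

test_that("marker-arm density and enrichment follow the 5% expression rule", {
  # 20 cells; geneX detected in 1 cell of 25 -> 4% -> not expressed
  ng <- 40
  m <- matrix(0L, ng, 25)
  m[1:20, ] <- 1L                      # 20 genes expressed everywhere
  m[21, 1] <- 1L                       # 4% detection
  x <- toy_counts(m)
  x$genes$chromosome <- rep(c("1", "2"), each = 20)
  res <- marker_arm_enrichment(x$genes$gene_id[c(1:5, 21)], x,
                               min_expr_frac = 0.05)
  r1 <- res[res$arm == "1q", ]
  expect_equal(r1$n_expressed, 20)
  expect_equal(r1$n_markers, 5)       # the 4% gene does not count
  expect_equal(r1$density, 0.25)
  # arm with 10 expressed, 5 markers -> density 0.5
  m2 <- matrix(1L, 20, 25)
  x2 <- toy_counts(m2)
  x2$genes$chromosome <- rep(c("1", "2"), each = 10)
  res2 <- marker_arm_enrichment(x2$genes$gene_id[1:5], x2)
  expect_equal(res2$density[res2$arm == "1q"], 0.5)
})

test_that("uniformly placed markers show no arm enrichment", {
  sim <- sim_small()
  counts <- sc_subset(sim$data,
                      cells = which(sim$data$cells$true_cell_type == "epithelial"))
  clean_hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    fake_markers <- sample(counts$genes$gene_id[!counts$genes$is_mito], 100)
    res <- marker_arm_enrichment(fake_markers, counts)
    if (!any(res$q < 0.05, na.rm = TRUE)) clean_hits <- clean_hits + 1L
  }
  expect_gte(clean_hits, 9L)
})

test_that("marker-CNV concordance applies the direction rule", {
  genes <- gene_annotation(data.frame(
    gene_id = paste0("g", 1:6),
    chromosome = c("8", "8", "17", "17", "5", "5"),
    arm = c("q", "q", "p", "p", "q", "q"),
    start_bp = 1:6, is_mito = FALSE))
  sig <- signature_set(list(
    i2 = list(up = c("g1", "g3"), down = c("g2", "g4")),
    i3 = list(up = "g5", down = "g6")))
  calls <- c("8q" = "gain", "17p" = "loss", "5q" = "neutral")
  res <- marker_cnv_concordance(sig, calls, genes)
  tab <- res$table
  expect_equal(res$n_on_called_arms, 4)      # neutral-arm genes excluded
  expect_true(tab$concordant[tab$gene_id == "g1"])   # Up on gained arm
  expect_false(tab$concordant[tab$gene_id == "g2"])  # Down on gained arm
  expect_false(tab$concordant[tab$gene_id == "g3"])  # Up on lost arm
  expect_true(tab$concordant[tab$gene_id == "g4"])   # Down on lost arm
  expect_equal(res$concordance, 0.5)
  expect_error(marker_cnv_concordance(sig, c("5q" = "neutral"), genes),
               "no signature genes")
})

test_that("planted concordant fraction is recovered on generator truth", {
  fx <- cnv_fixture()
  epi <- fx$epi
  sim <- sim_small()
  gt <- sim$truth$gene_truth
  truth_sig <- signature_set(list(
    i2 = list(up = gt$gene_id[gt$marker_class == "i2" & gt$marker_dir == "Up"],
              down = gt$gene_id[gt$marker_class == "i2" & gt$marker_dir == "Down"]),
    i3 = list(up = gt$gene_id[gt$marker_class == "i3" & gt$marker_dir == "Up"],
              down = gt$gene_id[gt$marker_class == "i3" & gt$marker_dir == "Down"])))
  i2_cells <- epi$cells$cell_id[epi$cells$true_subtype == "i2"]
  prof_i2 <- fx$profile
  prof_i2$scores <- prof_i2$scores[i2_cells, ]
  arm <- arm_level_summary(prof_i2, groups = rep("i2", length(i2_cells)))
  res <- marker_cnv_concordance(truth_sig, arm$calls["i2", ], epi$genes)
  expect_equal(res$concordance, 0.9, tolerance = 0.075)
})
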
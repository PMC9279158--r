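# Shared fixtures, built in code and memoised across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Small multi-cohort simulation for module tests.
sim_small <- function() memo("sim_small", {
  simulate_sc_cohorts(sim_config(
    n_cohorts = 2, patients_per_cohort = 3, cells_per_sample = 300,
    normal_cells_per_sample = 200, seed = 101))
})

# Mid-size multi-cohort simulation, large enough for the full pipeline
# (the pseudo-bulk NB stage needs several patients per subtype).
sim_mid <- function() memo("sim_mid", {
  simulate_sc_cohorts(sim_config(
    n_cohorts = 3, patients_per_cohort = 4, cells_per_sample = 350,
    normal_cells_per_sample = 230, seed = 303))
})

# Single large discovery cohort (14 patients, like a well-powered
# discovery dataset) for the pseudo-bulk split / stage-one marker tests.
sim_disc <- function() memo("sim_disc", {
  simulate_sc_cohorts(sim_config(
    n_cohorts = 1, patients_per_cohort = 14, cells_per_sample = 280,
    normal_cells_per_sample = 180, subtype_fractions = c(i2 = 9 / 14, i3 = 5 / 14),
    low_quality_sample_frac = 0, seed = 202))
})

# QC'd epithelial log-norm view of sim_small with truth-typed cells.
epi_small <- function() memo("epi_small", {
  sim <- sim_small()
  keep <- with(sim$data$cells,
               !is_doublet & !is_low_quality & true_cell_type == "epithelial" &
                 !sample_id %in% sim$truth$samples$sample_id[sim$truth$samples$is_degraded])
  lognormalize(sc_subset(sim$data, cells = which(keep)))
})

adjusted_rand_index_test <- function(a, b) icmskit:::adjusted_rand_index(a, b)
match_accuracy_test <- function(a, b) icmskit:::match_accuracy(a, b)

# Minimal hand-built sc_counts: counts matrix given directly, one sample.
toy_counts <- function(m, tissue = "tumor", sample_id = NULL, mito = NULL) {
  m <- as.matrix(m)
  ng <- nrow(m); nc <- ncol(m)
  if (is.null(sample_id)) sample_id <- rep("s1", nc)
  genes <- gene_annotation(data.frame(
    gene_id = sprintf("g%03d", seq_len(ng)),
    chromosome = "1", arm = "q", start_bp = seq_len(ng) * 1000L,
    is_mito = if (is.null(mito)) rep(FALSE, ng) else mito))
  cells <- data.frame(cell_id = sprintf("c%03d", seq_len(nc)),
                      sample_id = sample_id,
                      patient_id = sub("s", "p", sample_id),
                      cohort_id = "cohortX",
                      tissue = rep(tissue, length.out = nc))
  sc_counts(m, cells, genes)
}
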
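test_that("simulation is deterministic given the seed", {
  cfg <- uniform_motif_config(3, -0.8, 0.8, seed = 5, scale = "raw")
  a <- simulate_profiles(cfg)
  b <- simulate_profiles(cfg)
  expect_identical(a$tf$values, b$tf$values)
  expect_identical(a$gene$values, b$gene$values)
  expect_identical(a$meth$values, b$meth$values)
  expect_identical(a$truth, b$truth)
  d <- simulate_profiles(uniform_motif_config(3, -0.8, 0.8, seed = 6, scale = "raw"))
  expect_false(identical(a$meth$values, d$meth$values))
})

test_that("with no planted motifs all case TF-gene correlations are near zero", {
  cfg <- simulation_config(n_tf = 20, n_gene = 20, n_meth = 5,
                           n_case = 30, scale = "log2", seed = 9)
  sim <- simulate_profiles(cfg)
  tfv <- case_values(sim$tf)
  gnv <- case_values(sim$gene)
  r <- as.vector(cor(t(tfv), t(gnv)))
  # null correlations: sd approx 1/sqrt(29); the mean of 400 |r| must be small
  expect_lt(mean(abs(r)), 0.25)
  expect_lt(abs(mean(r)), 0.05)
  expect_equal(nrow(sim$truth$motifs), 0)
})

test_that("planted motifs reproduce their stratified correlations (plant fidelity)", {
  # average the estimator over 3 seeds at n_case = 300 (per-seed sd ~0.05)
  est <- sapply(21:23, function(s) {
    cfg <- uniform_motif_config(2, -0.6, 0.7, n_case = 300, seed = s)
    sim <- simulate_profiles(cfg)
    cids <- case_ids(sim$meth)
    unlist(lapply(1:2, function(i) {
      mo <- sim$truth$motifs[i, ]
      st <- stratify_samples(setNames(case_values(sim$meth)[mo$site, ], cids))
      dc <- delta_correlation(setNames(case_values(sim$tf)[mo$tf, ], cids),
                              setNames(case_values(sim$gene)[mo$gene, ], cids),
                              st)
      c(dc$r_low, dc$r_high)
    }))
  })
  m <- rowMeans(est)
  expect_lt(abs(m[1] - (-0.6)), 0.1)
  expect_lt(abs(m[2] - 0.7), 0.1)
  expect_lt(abs(m[3] - (-0.6)), 0.1)
  expect_lt(abs(m[4] - 0.7), 0.1)
})

test_that("strong reverse plants land in the right tails for >= 95% of seeds", {
  hits <- 0L
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    sim <- simulate_profiles(uniform_motif_config(1, 0.9, -0.9, seed = s))
    cids <- case_ids(sim$meth)
    st <- stratify_samples(setNames(case_values(sim$meth)[1, ], cids))
    dc <- delta_correlation(setNames(case_values(sim$tf)[1, ], cids),
                            setNames(case_values(sim$gene)[1, ], cids), st)
    if (dc$r_low >= 0.6 && dc$r_high <= -0.6) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("differential plants shift case methylation; null sites do not", {
  cfg <- simulation_config(n_tf = 2, n_gene = 2, n_meth = 10, n_case = 30,
                           planted_motifs = list(
                             planted_motif(1, 1, 1, -0.5, 0.5, differential = TRUE),
                             planted_motif(2, 2, 2, -0.5, 0.5, differential = FALSE)),
                           seed = 33)
  sim <- simulate_profiles(cfg)
  gap <- abs(rowMeans(case_values(sim$meth)) - rowMeans(control_values(sim$meth)))
  expect_gt(gap[1], 0.15)        # differential site: mean shift ~0.3
  expect_lt(max(gap[3:10]), 0.15)  # null sites
  expect_identical(sim$truth$diff_sites, "cg000001")
  # beta-value range
  expect_true(all(sim$meth$values >= 0 & sim$meth$values <= 1))
})

test_that("config validation rejects malformed designs", {
  expect_error(planted_motif(1, 1, 1, r_low = 1, r_high = 0), "infeasible")
  expect_error(planted_motif(1, 1, 1, r_low = 0, r_high = -1.2), "infeasible")
  expect_error(uniform_motif_config(2, 0.5, 0.5, n_case = 4), "at least 5")
  expect_error(
    simulation_config(n_tf = 1, n_gene = 1, n_meth = 1,
                      planted_motifs = list(planted_motif(2, 1, 1, 0.5, 0.5))),
    "out-of-range")
  expect_error(
    simulation_config(n_tf = 2, n_gene = 2, n_meth = 1,
                      planted_motifs = list(planted_motif(1, 1, 1, 0.5, 0.5),
                                            planted_motif(1, 2, 2, 0.4, 0.4))),
    "at most one")
})

test_that("interaction catalog contains plants plus unique decoys, deterministically", {
  motifs <- lapply(1:4, function(i) planted_motif(i, i, i, -0.5, 0.5))
  cfg <- simulation_config(n_tf = 10, n_gene = 10, n_meth = 4,
                           planted_motifs = motifs, seed = 2)
  sim <- simulate_profiles(cfg)
  cat0 <- simulate_interaction_catalog(sim$truth, n_extra = 0, seed = 7)
  expect_identical(cat0, unique(sim$truth$corr_pairs))
  cat20 <- simulate_interaction_catalog(sim$truth, n_extra = 20, seed = 7)
  expect_equal(nrow(cat20), 4 + 20)
  expect_equal(anyDuplicated(paste(cat20$tf, cat20$gene)), 0)
  expect_identical(cat20, simulate_interaction_catalog(sim$truth, 20, seed = 7))
  # the 10x10 universe minus 4 planted pairs cannot supply 97 decoys
  expect_error(simulate_interaction_catalog(sim$truth, n_extra = 97, seed = 7),
               "decoy")
})

test_that("annotation files have the constructed enrichment and hub degree", {
  genes <- sprintf("G%05d", 1:10)
  background <- c(genes, sprintf("BG%04d", 1:90))
  gmt_path <- tempfile(fileext = ".gmt")
  drug_path <- tempfile(fileext = ".tsv")
  ann <- simulate_annotation_files(genes, seed = 4, background = background,
                                   hub_targets = 7,
                                   gmt_path = gmt_path, drug_path = drug_path)
  # GMT roundtrip
  sets <- read_gmt(gmt_path)
  expect_identical(sets$SET_ENRICHED, ann$gene_sets$SET_ENRICHED)
  # designated set is all query genes: hypergeometric tail is tiny at N = 100
  rec <- fisher_enrichment(genes, sets, background)
  expect_lt(rec$p[rec$set_name == "SET_ENRICHED"], 0.05)
  expect_equal(rec$overlap_count[rec$set_name == "SET_ENRICHED"], 10)
  # designated drug has its constructed degree downstream
  motifs <- data.frame(tf = genes[1:5], gene = genes[6:10], site = "cg1")
  dn <- build_drug_network(motifs, read_drug_catalog(drug_path))
  expect_equal(dn$drug_degrees$degree[dn$drug_degrees$drug == "DRUG_HUB"], 7)
  # empty drug catalog is a valid empty table
  empty <- simulate_annotation_files(genes, seed = 4, n_drugs = 0)
  expect_equal(nrow(empty$drug_catalog), 0)
  p2 <- tempfile(fileext = ".tsv")
  write_tsv(empty$drug_catalog, p2)
  expect_equal(nrow(read_drug_catalog(p2)), 0)
})
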
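# case-only matrices whose strata have exactly representable correlations:
# 10 case samples, fraction 0.4 -> low = case_01..04, high = case_07..10
exact_strata_matrices <- function() {
  cases <- sprintf("case_%02d", 1:10)
  ctrls <- sprintf("ctrl_%02d", 1:5)
  labs <- setNames(rep(c("case", "control"), c(10, 5)), c(cases, ctrls))
  meth <- matrix(seq(0.05, 0.95, length.out = 10), nrow = 1,
                 dimnames = list("cgE", cases))
  tf <- matrix(c(1, 2, 3, 4, 9, 9.5, 1, 2, 3, 4), nrow = 1,
               dimnames = list("TFE", cases))
  # low stratum: gene = (1,3,2,4) vs tf (1,2,3,4) -> r = 0.8 exactly
  # high stratum: gene = (4,2,3,1) -> r = -0.8 exactly; delta = -1.6
  gene <- matrix(c(1, 3, 2, 4, 7, 7.5, 4, 2, 3, 1), nrow = 1,
                 dimnames = list("GE", cases))
  pad <- function(x) {
    out <- cbind(x, matrix(seq_len(nrow(x) * 5) / 10, nrow(x), 5))
    colnames(out) <- c(cases, ctrls)
    out
  }
  list(tf = omics_matrix(pad(tf), labs),
       gene = omics_matrix(pad(gene), labs),
       meth = omics_matrix(pad(meth), labs))
}

test_that("stratification takes the floor(fraction n) tails with ID tie-breaks", {
  x <- setNames(runif(30), sprintf("case_%03d", 1:30))
  st <- stratify_samples(x, 0.4)
  expect_length(st$low_ids, 12)
  expect_length(st$high_ids, 12)
  expect_length(intersect(st$low_ids, st$high_ids), 0)
  expect_true(max(x[st$low_ids]) <= min(x[st$high_ids]))

  v <- setNames(1:10, sprintf("s%02d", 1:10))
  st <- stratify_samples(v, 0.4)
  expect_equal(st$low_ids, sprintf("s%02d", 1:4))
  expect_equal(st$high_ids, sprintf("s%02d", 7:10))

  # all tied: purely sample-ID order, sizes still floor(0.4 n)
  tied <- setNames(rep(0.5, 10), sprintf("s%02d", 10:1))
  st <- stratify_samples(tied, 0.4)
  expect_equal(st$low_ids, sprintf("s%02d", 1:4))
  expect_equal(st$high_ids, sprintf("s%02d", 7:10))

  expect_error(stratify_samples(v, 0), "\\(0, 0.5\\]")
  expect_error(stratify_samples(v, 0.6), "\\(0, 0.5\\]")
  # monotone-transform invariance (log2 preprocessing cannot change strata)
  y <- setNames(runif(20, 0.01, 0.99), sprintf("c%02d", 1:20))
  expect_identical(stratify_samples(y), stratify_samples(log2(y)))
})

test_that("delta_correlation is antisymmetric under stratum swap and bounded", {
  m <- exact_strata_matrices()
  cids <- case_ids(m$meth)
  st <- stratify_samples(setNames(case_values(m$meth)[1, ], cids))
  tfr <- setNames(case_values(m$tf)[1, ], cids)
  gnr <- setNames(case_values(m$gene)[1, ], cids)
  dc <- delta_correlation(tfr, gnr, st)
  expect_equal(dc$r_low, 0.8)
  expect_equal(dc$r_high, -0.8)
  expect_equal(dc$delta, -1.6)
  swapped <- structure(list(low_ids = st$high_ids, high_ids = st$low_ids),
                       class = "stratification")
  expect_equal(delta_correlation(tfr, gnr, swapped)$delta, 1.6)
  expect_lte(abs(dc$delta), 2)
})

test_that("candidate screen keeps |delta| strictly above the threshold", {
  m <- exact_strata_matrices()
  inter <- data.frame(tf = "TFE", gene = "GE")
  # |delta| = 1.6 exactly: dropped at 1.6, kept at 1.59
  out <- candidate_motifs(inter, "cgE", m$tf, m$gene, m$meth,
                          delta_threshold = 1.6)
  expect_equal(nrow(out), 0)
  expect_equal(nrow(attr(out, "tested")), 1)
  out <- candidate_motifs(inter, "cgE", m$tf, m$gene, m$meth,
                          delta_threshold = 1.59)
  expect_equal(nrow(out), 1)
  expect_equal(out$delta, -1.6)
})

test_that("untestable motifs are excluded with a reason", {
  m <- exact_strata_matrices()
  tfv <- m$tf$values
  tfv <- rbind(tfv, TFC = c(rep(1, 10), 1:5))  # constant across cases
  m$tf <- omics_matrix(tfv, m$tf$labels)
  inter <- data.frame(tf = c("TFE", "TFC", "TFZ"), gene = "GE")
  out <- candidate_motifs(inter, "cgE", m$tf, m$gene, m$meth,
                          delta_threshold = 0.5)
  un <- attr(out, "untestable")
  expect_equal(nrow(out), 1)
  expect_setequal(un$tf, c("TFC", "TFZ"))
  expect_match(un$reason[un$tf == "TFC"], "degenerate")
  expect_equal(un$reason[un$tf == "TFZ"], "missing_feature")
})

test_that("empty upstream inputs give an empty candidate set with a warning", {
  m <- exact_strata_matrices()
  expect_warning(
    out <- candidate_motifs(data.frame(tf = character(), gene = character()),
                            character(), m$tf, m$gene, m$meth),
    "empty")
  expect_equal(nrow(out), 0)
})

test_that("permutation p has add-one support and is seed-deterministic", {
  m <- exact_strata_matrices()
  motif <- list(site = "cgE", tf = "TFE", gene = "GE")
  p1 <- permutation_test(motif, m$tf, m$gene, m$meth, n_perm = 99, seed = 5)
  p2 <- permutation_test(motif, m$tf, m$gene, m$meth, n_perm = 99, seed = 5)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 100)          # can never be 0

  # a strongly modulated motif at n_case = 30 sits at or near the p floor
  sim <- simulate_profiles(uniform_motif_config(1, 0.9, -0.9, seed = 41))
  pr <- permutation_test(list(site = "cg000001", tf = "TF0001", gene = "G00001"),
                         sim$tf, sim$gene, sim$meth, n_perm = 99, seed = 6)
  expect_lte(pr, 5 / 100)
  expect_gte(pr, 1 / 100)

  # delta exactly 0 (gene identical to tf): every permutation ties -> p = 1
  m2 <- exact_strata_matrices()
  gv <- m2$tf$values
  rownames(gv) <- "GE"
  m2$gene <- omics_matrix(gv, m2$gene$labels)
  expect_equal(permutation_test(motif, m2$tf, m2$gene, m2$meth,
                                n_perm = 50, seed = 1), 1)
})

test_that("detection is independent of motif iteration order", {
  sim <- simulate_profiles(uniform_motif_config(6, 0.8, -0.8, seed = 23))
  cand <- candidate_motifs(sim$truth$corr_pairs, sim$truth$motifs$site,
                           sim$tf, sim$gene, sim$meth,
                           combos = sim$truth$motifs[, c("site", "tf", "gene")])
  fwd <- detect_methtdms(cand, sim$tf, sim$gene, sim$meth, n_perm = 99, seed = 3)
  rev_cand <- cand[rev(seq_len(nrow(cand))), ]
  bwd <- detect_methtdms(rev_cand, sim$tf, sim$gene, sim$meth, n_perm = 99, seed = 3)
  expect_identical(fwd, bwd, ignore_attr = TRUE)
})

test_that("planted reverse motifs are recovered as candidates across seeds", {
  for (s in 1:5) {
    sim <- simulate_profiles(uniform_motif_config(20, 0.8, -0.8, seed = 300 + s))
    cand <- candidate_motifs(sim$truth$corr_pairs, sim$truth$motifs$site,
                             sim$tf, sim$gene, sim$meth,
                             combos = sim$truth$motifs[, c("site", "tf", "gene")])
    expect_equal(nrow(cand), 20,
                 label = sprintf("seed %d: all 20 planted motifs pass |delta| > 0.7", s))
  }
})

test_that("significant motifs are sorted deterministically and FDR-filtered", {
  sim <- simulate_profiles(uniform_motif_config(8, 0.85, -0.85, seed = 31))
  cand <- candidate_motifs(sim$truth$corr_pairs, sim$truth$motifs$site,
                           sim$tf, sim$gene, sim$meth,
                           combos = sim$truth$motifs[, c("site", "tf", "gene")])
  sig <- detect_methtdms(cand, sim$tf, sim$gene, sim$meth, n_perm = 199, seed = 4)
  expect_equal(nrow(sig), 8)
  expect_true(all(sig$q < 0.05))
  expect_true(all(diff(sig$q) >= 0))
  expect_equal(sig$q, bh_fdr(attr(sig, "tested")$p_perm)[
    match(paste(sig$site, sig$tf, sig$gene),
          paste(attr(sig, "tested")$site, attr(sig, "tested")$tf,
                attr(sig, "tested")$gene))])
})
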
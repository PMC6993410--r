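#' Stratify case samples by methylation level
#'
#' Case samples are ranked ascending by the site's methylation value
#' (ties broken by sample ID, so the split is deterministic); the low
#' stratum is the first `floor(fraction * n)` samples and the high
#' stratum the last `floor(fraction * n)`. With 30 case samples and the
#' default fraction this gives the 12-vs-12 top/bottom-40% split.
#' Because ranking is invariant under strictly monotone transforms, the
#' strata do not depend on whether methylation was log2-transformed.
#'
#' @param meth_row Named numeric vector of one site's methylation values
#'   over the case samples.
#' @param fraction Tail fraction in `(0, 0.5]` (default 0.4).
#' @return A `stratification` list with `low_ids` and `high_ids`.
#' @export
stratify_samples <- function(meth_row, fraction = 0.4) {
  if (is.null(names(meth_row))) stop("'meth_row' must be named by sample ID")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5) {
    stop("'fraction' must lie in (0, 0.5]")
  }
  n <- length(meth_row)
  if (n < 5) stop("need at least 5 case samples to stratify")
  k <- floor(fraction * n)
  if (k < 3) stop("stratum size below 3; increase 'fraction' or sample count")
  ord <- order(meth_row, names(meth_row))
  structure(list(low_ids = names(meth_row)[ord[seq_len(k)]],
                 high_ids = names(meth_row)[ord[seq.int(n - k + 1L, n)]]),
            class = "stratification")
}

#' Stratified correlation difference for one motif
#'
#' Pearson correlation of the TF-gene pair within each methylation
#' stratum, and their difference `delta = r_high - r_low`.
#'
#' @param tf_row,gene_row Named numeric expression vectors covering all
#'   stratum sample IDs.
#' @param strat A [stratify_samples()] result.
#' @return List `r_low`, `r_high`, `delta`. Degenerate within-stratum
#'   variance raises an error; callers testing many motifs catch it and
#'   record the motif as untestable.
#' @export
delta_correlation <- function(tf_row, gene_row, strat) {
  stopifnot(inherits(strat, "stratification"))
  r_low <- pearson(tf_row[strat$low_ids], gene_row[strat$low_ids])
  r_high <- pearson(tf_row[strat$high_ids], gene_row[strat$high_ids])
  list(r_low = r_low, r_high = r_high, delta = r_high - r_low)
}

#' Enumerate and screen candidate methTDMs
#'
#' Crosses every retained differential site with every retained TF-gene
#' interaction (or an explicit `combos` table), computes the stratified
#' correlation difference for each motif, and keeps motifs with
#' `|delta| > delta_threshold` (strict). Motifs that cannot be tested
#' (missing feature rows, constant expression within a stratum) are
#' excluded with a reason in `attr(, "untestable")`; the full tested
#' table is in `attr(, "tested")`.
#'
#' @param interactions Data frame with columns `tf`, `gene` (e.g. from
#'   [pe_specific_interactions()]).
#' @param sites Character vector of site IDs, or a data frame with a
#'   `site` column (e.g. from [differential_methylation()]).
#' @param tf_m,gene_m,meth_m The three [omics_matrix] inputs.
#' @param fraction Stratification tail fraction (default 0.4).
#' @param delta_threshold Candidate threshold on `|delta|` (default 0.7).
#' @param combos Optional data frame `site`, `tf`, `gene` restricting the
#'   motif universe instead of the full cross.
#' @return Data frame `site`, `tf`, `gene`, `r_low`, `r_high`, `delta`.
#' @export
candidate_motifs <- function(interactions, sites, tf_m, gene_m, meth_m,
                             fraction = 0.4, delta_threshold = 0.7,
                             combos = NULL) {
  if (is.data.frame(sites)) sites <- sites$site
  sites <- unique(as.character(sites))
  if (is.null(combos)) {
    if (!length(sites) || !nrow(interactions)) {
      warning("empty site or interaction input; no candidate motifs")
      combos <- data.frame(site = character(), tf = character(),
                           gene = character(), stringsAsFactors = FALSE)
    } else {
      idx <- expand.grid(s = seq_along(sites),
                         i = seq_len(nrow(interactions)))
      combos <- data.frame(site = sites[idx$s],
                           tf = interactions$tf[idx$i],
                           gene = interactions$gene[idx$i],
                           stringsAsFactors = FALSE)
    }
  }
  if (anyDuplicated(paste(combos$site, combos$tf, combos$gene, sep = "\x1f"))) {
    stop("duplicate (site, tf, gene) motif keys")
  }
  cids <- case_ids(meth_m)
  tfv <- case_values(tf_m)
  gnv <- case_values(gene_m)
  mev <- case_values(meth_m)
  strat_cache <- list()
  n <- nrow(combos)
  r_low <- r_high <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- combos$site[i]; tf <- combos$tf[i]; gn <- combos$gene[i]
    if (!s %in% rownames(mev) || !tf %in% rownames(tfv) ||
        !gn %in% rownames(gnv)) {
      reason[i] <- "missing_feature"
      next
    }
    st <- strat_cache[[s]]
    if (is.null(st)) {
      st <- stratify_samples(setNames(mev[s, ], cids), fraction)
      strat_cache[[s]] <- st
    }
    res <- tryCatch(
      delta_correlation(setNames(tfv[tf, ], cids), setNames(gnv[gn, ], cids), st),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      reason[i] <- paste0("degenerate: ", res)
      next
    }
    r_low[i] <- res$r_low
    r_high[i] <- res$r_high
  }
  untestable <- data.frame(site = combos$site, tf = combos$tf,
                           gene = combos$gene, reason = reason,
                           stringsAsFactors = FALSE)[!is.na(reason), , drop = FALSE]
  rownames(untestable) <- NULL
  tested <- data.frame(site = combos$site, tf = combos$tf, gene = combos$gene,
                       r_low = r_low, r_high = r_high,
                       delta = r_high - r_low,
                       stringsAsFactors = FALSE)[is.na(reason), , drop = FALSE]
  rownames(tested) <- NULL
  out <- tested[abs(tested$delta) > delta_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "untestable") <- untestable
  attr(out, "tested") <- tested
  out
}

# Vectorized Pearson across rows of two conformable matrices; NaN where
# a row is constant.
.row_pearson <- function(X, Y) {
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  num <- rowSums(Xc * Yc)
  den <- sqrt(rowSums(Xc^2) * rowSums(Yc^2))
  num / den
}

# Null distribution of |delta| under random methylation-to-sample
# assignment. Degenerate replicates (constant expression in a permuted
# stratum) are redrawn up to max_tries total draws.
.perm_abs_delta <- function(tf, gene, meth, ids, k, n_perm,
                            max_tries = 10L * n_perm) {
  n <- length(meth)
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n_perm) {
    batch <- n_perm - length(out)
    if (tries + batch > max_tries) {
      stop("permutation cap exceeded: too many degenerate replicates")
    }
    low_idx <- matrix(0L, batch, k)
    high_idx <- matrix(0L, batch, k)
    for (j in seq_len(batch)) {
      assigned <- meth[sample.int(n)]
      ord <- order(assigned, ids)
      low_idx[j, ] <- ord[seq_len(k)]
      high_idx[j, ] <- ord[seq.int(n - k + 1L, n)]
    }
    r_lo <- .row_pearson(matrix(tf[low_idx], batch), matrix(gene[low_idx], batch))
    r_hi <- .row_pearson(matrix(tf[high_idx], batch), matrix(gene[high_idx], batch))
    d <- abs(r_hi - r_lo)
    out <- c(out, d[is.finite(d)])
    tries <- tries + batch
  }
  out[seq_len(n_perm)]
}

#' Permutation p value for one motif
#'
#' The null hypothesis is "methylation does not modulate the pair":
#' each permutation shuffles the assignment between the site's
#' methylation values and the case samples (TF and gene stay paired),
#' re-stratifies, and recomputes `|delta|`. The add-one estimator
#' `p = (1 + #\{perm |delta| >= observed\}) / (n_perm + 1)` is returned,
#' so p can never be 0. The motif's RNG seed derives from
#' `(seed, site, tf, gene)` via a stable hash, making results
#' independent of iteration order.
#'
#' @param motif List or one-row data frame with `site`, `tf`, `gene`.
#' @param tf_m,gene_m,meth_m The three [omics_matrix] inputs.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Master integer seed.
#' @param fraction Stratification tail fraction (default 0.4).
#' @return The permutation p value in `(0, 1]`.
#' @export
permutation_test <- function(motif, tf_m, gene_m, meth_m, n_perm = 1000,
                             seed = 1, fraction = 0.4) {
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  site <- as.character(motif$site)
  tf <- as.character(motif$tf)
  gene <- as.character(motif$gene)
  cids <- case_ids(meth_m)
  meth <- setNames(case_values(meth_m)[site, ], cids)
  tfr <- setNames(case_values(tf_m)[tf, ], cids)
  gnr <- setNames(case_values(gene_m)[gene, ], cids)
  st <- stratify_samples(meth, fraction)
  obs <- abs(delta_correlation(tfr, gnr, st)$delta)
  k <- length(st$low_ids)
  set.seed(stable_hash(seed, site, tf, gene))
  perm <- .perm_abs_delta(unname(tfr), unname(gnr), unname(meth), cids, k, n_perm)
  (1 + sum(perm >= obs)) / (n_perm + 1)
}

#' Significant methTDMs by permutation with FDR control
#'
#' Runs [permutation_test()] for every candidate motif, applies one
#' global Benjamini-Hochberg family across all candidates, and retains
#' motifs with `q < q_threshold` (strict), sorted by `q` ascending then
#' `|delta|` descending (then site, tf, gene for full determinism).
#'
#' @param candidates Output of [candidate_motifs()].
#' @param tf_m,gene_m,meth_m The three [omics_matrix] inputs.
#' @param n_perm Permutations per motif (default 1000).
#' @param seed Master integer seed.
#' @param q_threshold BH FDR threshold (default 0.05).
#' @param fraction Stratification tail fraction (default 0.4).
#' @return Data frame `site`, `tf`, `gene`, `r_low`, `r_high`, `delta`,
#'   `p_perm`, `q`; the full tested table (before the q filter) is in
#'   `attr(, "tested")`.
#' @export
detect_methtdms <- function(candidates, tf_m, gene_m, meth_m, n_perm = 1000,
                            seed = 1, q_threshold = 0.05, fraction = 0.4) {
  out <- candidates
  if (!nrow(out)) {
    out$p_perm <- numeric(0)
    out$q <- numeric(0)
    attr(out, "tested") <- out
    return(out)
  }
  p <- vapply(seq_len(nrow(out)), function(i) {
    permutation_test(out[i, ], tf_m, gene_m, meth_m,
                     n_perm = n_perm, seed = seed, fraction = fraction)
  }, 0)
  out$p_perm <- p
  out$q <- bh_fdr(p)
  tested <- out
  out <- out[out$q < q_threshold, , drop = FALSE]
  out <- out[order(out$q, -abs(out$delta), out$site, out$tf, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- tested
  out
}
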
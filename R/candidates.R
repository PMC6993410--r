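#' Screen for case-specific TF-gene interactions
#'
#' For every catalog pair, the Pearson correlation of TF and gene
#' expression is computed over the **case samples only**, and pairs with
#' `|r| > r_threshold` (strict) are retained. Pairs whose TF or gene is
#' missing from the matrices, or whose expression is constant across
#' case samples, are not an error: they are collected in a skipped-pairs
#' report attached as `attr(, "skipped")`.
#'
#' @param tf_m,gene_m [omics_matrix] of TF and gene expression over the
#'   same samples.
#' @param catalog Data frame with columns `tf` and `gene`.
#' @param r_threshold Retention threshold on `|r|` (default 0.25).
#' @return Data frame `tf`, `gene`, `r_case`, sorted by `|r_case|`
#'   descending, ties broken by (tf, gene) lexicographically; attribute
#'   `skipped` is a data frame `tf`, `gene`, `reason`.
#' @export
pe_specific_interactions <- function(tf_m, gene_m, catalog, r_threshold = 0.25) {
  stopifnot(inherits(tf_m, "omics_matrix"), inherits(gene_m, "omics_matrix"))
  if (!identical(sample_ids(tf_m), sample_ids(gene_m))) {
    stop("TF and gene matrices must share the same ordered samples")
  }
  ids <- case_ids(tf_m)
  if (length(ids) < 3) stop("need at least 3 case samples")
  catalog <- unique(catalog[, c("tf", "gene")])
  tfv <- case_values(tf_m)
  gnv <- case_values(gene_m)
  n <- nrow(catalog)
  r <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tf <- catalog$tf[i]
    gn <- catalog$gene[i]
    if (!tf %in% rownames(tfv) || !gn %in% rownames(gnv)) {
      reason[i] <- "missing_feature"
      next
    }
    x <- tfv[tf, ]
    y <- gnv[gn, ]
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      reason[i] <- "degenerate_variance"
      next
    }
    r[i] <- stats::cor(x, y)
  }
  skipped <- data.frame(tf = catalog$tf, gene = catalog$gene,
                        reason = reason,
                        stringsAsFactors = FALSE)[!is.na(reason), , drop = FALSE]
  rownames(skipped) <- NULL
  keep <- !is.na(r) & abs(r) > r_threshold
  out <- data.frame(tf = catalog$tf[keep], gene = catalog$gene[keep],
                    r_case = r[keep], stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r_case), out$tf, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Differential methylation screen
#'
#' Per-site pooled-variance two-sample t test (case vs control) with one
#' global Benjamini-Hochberg family across all testable sites; sites
#' with `q < q_threshold` (strict) are retained. Sites with zero pooled
#' variance are untestable and reported in `attr(, "skipped")`; the full
#' tested table is kept in `attr(, "all")`.
#'
#' @param meth_m [omics_matrix] of methylation values.
#' @param q_threshold BH FDR retention threshold (default 0.05).
#' @return Data frame `site`, `t`, `p`, `q`, `mean_case`, `mean_control`
#'   for retained sites, sorted by `q` then site ID.
#' @export
differential_methylation <- function(meth_m, q_threshold = 0.05) {
  stopifnot(inherits(meth_m, "omics_matrix"))
  a <- case_values(meth_m)
  b <- control_values(meth_m)
  if (ncol(a) < 2 || ncol(b) < 2) stop("each label group needs >= 2 samples")
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  ss1 <- rowSums((a - m1)^2)
  ss2 <- rowSums((b - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  testable <- sp2 > 0
  skipped <- data.frame(site = feature_ids(meth_m)[!testable],
                        reason = rep("degenerate_variance", sum(!testable)),
                        stringsAsFactors = FALSE)
  tstat <- (m1 - m2)[testable] / sqrt(sp2[testable] * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tstat), df)
  q <- bh_fdr(p)
  all_tab <- data.frame(site = feature_ids(meth_m)[testable],
                        t = unname(tstat), p = unname(p), q = unname(q),
                        mean_case = unname(m1[testable]),
                        mean_control = unname(m2[testable]),
                        stringsAsFactors = FALSE)
  out <- all_tab[all_tab$q < q_threshold, , drop = FALSE]
  out <- out[order(out$q, out$site), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "all") <- all_tab
  out
}
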
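#' The six regulation-pattern labels
#'
#' Relax/intensify/reverse crossed with the baseline direction
#' (activation when the TF-gene correlation is positive in the
#' low-methylation stratum, inhibition when negative).
#' @export
pattern_labels <- c("relax_inhibition", "intensify_inhibition",
                    "relax_activation", "intensify_activation",
                    "reverse_activation", "reverse_inhibition")

#' Classify a motif into one of six regulation patterns
#'
#' The low-methylation stratum is the baseline: `r_low < 0` means the TF
#' inhibits the gene, `r_low > 0` that it activates it. Methylation then
#' either weakens the action (relax: same sign, smaller magnitude),
#' strengthens it (intensify: same sign, larger magnitude), or inverts
#' it (reverse: opposite sign in the high stratum). Reverse labels need
#' only the sign flip; exact magnitude ties resolve to the relax label.
#' Motifs whose baseline direction is not callable (`|r_low| < tau`) get
#' `NA` and are reported separately by [classify_motifs()].
#'
#' @param r_low,r_high Stratified correlations (vectorized).
#' @param tau Minimum `|r_low|` for a callable baseline direction
#'   (default 0.25, reusing the interaction-screen threshold).
#' @return Character vector of labels from [pattern_labels], `NA` where
#'   unclassifiable.
#' @export
classify_pattern <- function(r_low, r_high, tau = 0.25) {
  .classify_with_baseline(r_low, r_low, r_high, tau)
}

# direction from `base` (either r_low or r_case); magnitude comparison
# always r_high vs r_low
.classify_with_baseline <- function(base, r_low, r_high, tau) {
  if (length(r_low) != length(r_high) || length(base) != length(r_low)) {
    stop("length mismatch")
  }
  out <- rep(NA_character_, length(r_low))
  callable <- is.finite(base) & is.finite(r_low) & is.finite(r_high) &
    abs(base) >= tau
  inh <- callable & base < 0
  act <- callable & base > 0
  out[inh & r_high > 0] <- "reverse_activation"
  out[inh & r_high <= 0 & abs(r_high) > abs(r_low)] <- "intensify_inhibition"
  out[inh & r_high <= 0 & abs(r_high) <= abs(r_low)] <- "relax_inhibition"
  out[act & r_high < 0] <- "reverse_inhibition"
  out[act & r_high >= 0 & abs(r_high) > abs(r_low)] <- "intensify_activation"
  out[act & r_high >= 0 & abs(r_high) <= abs(r_low)] <- "relax_activation"
  out
}

#' Attach pattern labels to significant motifs
#'
#' @param motifs Data frame of significant motifs with `r_low`, `r_high`
#'   columns (e.g. from [detect_methtdms()]).
#' @param tau Direction-call threshold, see [classify_pattern()].
#' @param baseline Which correlation carries the baseline direction:
#'   the low-methylation stratum (default) or, behind a flag, the
#'   all-case correlation in a `r_case` column.
#' @return `motifs` with a `pattern` column (`NA` = unclassifiable);
#'   unclassifiable rows are also collected in `attr(, "unclassifiable")`.
#' @export
classify_motifs <- function(motifs, tau = 0.25,
                            baseline = c("r_low", "r_case")) {
  baseline <- match.arg(baseline)
  if (baseline == "r_case" && !"r_case" %in% names(motifs)) {
    stop("baseline 'r_case' requested but no r_case column present")
  }
  lab <- .classify_with_baseline(motifs[[baseline]], motifs$r_low,
                                 motifs$r_high, tau)
  motifs$pattern <- lab
  attr(motifs, "unclassifiable") <-
    motifs[is.na(lab), setdiff(names(motifs), "pattern"), drop = FALSE]
  motifs
}

.classified <- function(motifs) {
  if (!"pattern" %in% names(motifs)) stop("motifs are not classified yet")
  motifs[!is.na(motifs$pattern), , drop = FALSE]
}

#' Pattern distribution of classified motifs
#'
#' @param motifs Classified motif data frame (see [classify_motifs()]).
#' @return List with `counts` and `fractions` (both named by
#'   [pattern_labels]), `n_classified`, and `n_unclassified`. Fractions
#'   are over classified motifs and are `NA` when none are classified.
#' @export
pattern_distribution <- function(motifs) {
  cl <- .classified(motifs)
  counts <- table(factor(cl$pattern, levels = pattern_labels))
  counts <- setNames(as.integer(counts), pattern_labels)
  n <- sum(counts)
  fractions <- if (n > 0) counts / n else setNames(rep(NA_real_, 6), pattern_labels)
  list(counts = counts, fractions = fractions,
       n_classified = n, n_unclassified = sum(is.na(motifs$pattern)))
}

.pair_key <- function(tf, gene) paste(tf, gene, sep = "|")

#' Cross-pattern overlap of TF-gene pairs and sites
#'
#' For each unordered pair of labels, the number of shared TF-gene pairs
#' and shared sites; an element belongs to a label when at least one
#' motif with that label involves it. Diagonals hold per-label totals of
#' distinct elements.
#'
#' @inheritParams pattern_distribution
#' @return List of two symmetric 6x6 integer matrices, `pairs` and
#'   `sites`.
#' @export
cross_pattern_overlap <- function(motifs) {
  cl <- .classified(motifs)
  pair_sets <- lapply(pattern_labels, function(l) {
    sel <- cl$pattern == l
    unique(.pair_key(cl$tf[sel], cl$gene[sel]))
  })
  site_sets <- lapply(pattern_labels, function(l) unique(cl$site[cl$pattern == l]))
  overlap <- function(sets) {
    m <- matrix(0L, 6, 6, dimnames = list(pattern_labels, pattern_labels))
    for (i in 1:6) for (j in 1:6) {
      m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
    m
  }
  list(pairs = overlap(pair_sets), sites = overlap(site_sets))
}

#' Distinct-pattern frequency per site and per TF-gene pair
#'
#' @inheritParams pattern_distribution
#' @return List with data frames `sites` (`site`, `n_patterns`) and
#'   `pairs` (`tf`, `gene`, `n_patterns`), each sorted by decreasing
#'   frequency, plus `fraction_sites_multi` / `fraction_pairs_multi`,
#'   the fraction of elements participating in two or more distinct
#'   patterns.
#' @export
element_pattern_frequency <- function(motifs) {
  cl <- .classified(motifs)
  site_n <- tapply(cl$pattern, cl$site, function(x) length(unique(x)))
  pair_n <- tapply(cl$pattern, .pair_key(cl$tf, cl$gene),
                   function(x) length(unique(x)))
  sites <- data.frame(site = names(site_n), n_patterns = as.integer(site_n),
                      stringsAsFactors = FALSE)
  sites <- sites[order(-sites$n_patterns, sites$site), , drop = FALSE]
  rownames(sites) <- NULL
  pk <- names(pair_n)
  split_pk <- strsplit(pk, "|", fixed = TRUE)
  pairs <- data.frame(tf = vapply(split_pk, `[[`, "", 1L),
                      gene = vapply(split_pk, `[[`, "", 2L),
                      n_patterns = as.integer(pair_n),
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$n_patterns, pairs$tf, pairs$gene), , drop = FALSE]
  rownames(pairs) <- NULL
  list(sites = sites, pairs = pairs,
       fraction_sites_multi = if (nrow(sites)) mean(sites$n_patterns >= 2) else NA_real_,
       fraction_pairs_multi = if (nrow(pairs)) mean(pairs$n_patterns >= 2) else NA_real_)
}
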
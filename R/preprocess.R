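#' Matrix-cleaning rules for expression and methylation profiles
#'
#' The cleaning pipeline mirrors common practice for processed array
#' downloads: features that are zero in every sample are removed, any
#' remaining zeros are imputed with the smallest nonzero value of the
#' whole matrix, values are log2-transformed, and multi-probe features
#' are averaged to one row per gene symbol.
#'
#' @param m An [omics_matrix].
#' @return A cleaned [omics_matrix]; sample columns are never reordered
#'   or dropped.
#' @name preprocess
NULL

#' @rdname preprocess
#' @export
drop_all_zero_rows <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (nrow(m$values) == 0) stop("empty matrix")
  keep <- rowSums(m$values != 0) > 0
  if (!any(keep)) stop("all rows are zero in every sample; nothing left")
  .with_values(m, m$values[keep, , drop = FALSE])
}

#' @rdname preprocess
#' @export
impute_zeros_min <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  nz <- v[v != 0]
  if (!length(nz)) stop("all-zero matrix: no nonzero minimum to impute with")
  v[v == 0] <- min(nz)
  .with_values(m, v)
}

#' @rdname preprocess
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  bad <- which(v <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("nonpositive value %g at feature '%s', sample '%s'; run impute_zeros_min first",
                 v[bad[1, 1], bad[1, 2]],
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
  }
  .with_values(m, log2(v))
}

#' Average multi-probe features to one row per gene symbol
#'
#' @param m An [omics_matrix] whose rows are probes.
#' @param probe_map Data frame with columns `probe` and `symbol`;
#'   many probes may map to one symbol, each probe to exactly one.
#' @return An [omics_matrix] with one row per symbol, each cell the
#'   arithmetic mean of that symbol's probe rows; row order is the
#'   first-appearance order of symbols along the probe rows.
#' @export
collapse_probes <- function(m, probe_map) {
  stopifnot(inherits(m, "omics_matrix"))
  if (!all(c("probe", "symbol") %in% names(probe_map))) {
    stop("'probe_map' must have columns 'probe' and 'symbol'")
  }
  if (anyDuplicated(probe_map$probe)) stop("probe map assigns a probe twice")
  sym <- setNames(as.character(probe_map$symbol), as.character(probe_map$probe))
  unmapped <- setdiff(feature_ids(m), names(sym))
  if (length(unmapped)) {
    stop("unmapped probes: ", paste(unmapped, collapse = ", "))
  }
  groups <- sym[feature_ids(m)]
  sums <- rowsum(m$values, group = groups, reorder = FALSE)
  counts <- as.vector(table(factor(groups, levels = rownames(sums))))
  .with_values(m, sums / counts)
}

#' Run the full cleaning pipeline on one matrix
#'
#' Applies [drop_all_zero_rows()], [impute_zeros_min()], optionally
#' [log2_transform()], and [collapse_probes()] when a probe map is given.
#' The log2 step is applied to expression and methylation alike by
#' default (it is strictly monotone, so downstream quantile
#' stratification is unaffected); set `log2 = FALSE` to keep methylation
#' on the beta-value scale.
#'
#' @inheritParams collapse_probes
#' @param log2 Apply the log2 transform (default `TRUE`).
#' @export
preprocess_matrix <- function(m, probe_map = NULL, log2 = TRUE) {
  m <- drop_all_zero_rows(m)
  m <- impute_zeros_min(m)
  if (log2) m <- log2_transform(m)
  if (!is.null(probe_map)) m <- collapse_probes(m, probe_map)
  m
}
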
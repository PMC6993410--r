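#' Feature-by-sample omics matrix with case/control labels
#'
#' Shared container for the three input profiles (TF expression, gene
#' expression, methylation beta values). Rows are features, columns are
#' samples; every sample carries a `"case"` or `"control"` label.
#'
#' @param values Numeric matrix with unique row names (feature IDs) and
#'   unique column names (sample IDs).
#' @param labels Named character vector mapping every sample ID to
#'   `"case"` or `"control"`. Extra entries are ignored; missing entries
#'   are an error.
#' @return An object of class `omics_matrix`: a list with elements
#'   `values` (the matrix) and `labels` (reordered to match the columns).
#' @export
omics_matrix <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have feature row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  labels <- .check_labels(labels, colnames(values))
  structure(list(values = values, labels = labels), class = "omics_matrix")
}

.check_labels <- function(labels, sample_ids) {
  if (is.factor(labels)) labels <- setNames(as.character(labels), names(labels))
  if (is.null(names(labels))) stop("'labels' must be named by sample ID")
  missing <- setdiff(sample_ids, names(labels))
  if (length(missing)) {
    stop("labels missing for samples: ", paste(missing, collapse = ", "))
  }
  labels <- labels[sample_ids]
  bad <- !labels %in% c("case", "control")
  if (any(bad)) {
    stop("labels must be 'case' or 'control'; offending samples: ",
         paste(sample_ids[bad], collapse = ", "))
  }
  labels
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d features x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Accessors for omics_matrix components
#'
#' @param m An [omics_matrix].
#' @return Character vectors of IDs, or (for [case_values]/[control_values])
#'   the value sub-matrix restricted to one label group.
#' @name omics-accessors
NULL

#' @rdname omics-accessors
#' @export
feature_ids <- function(m) rownames(m$values)

#' @rdname omics-accessors
#' @export
sample_ids <- function(m) colnames(m$values)

#' @rdname omics-accessors
#' @export
case_ids <- function(m) names(m$labels)[m$labels == "case"]

#' @rdname omics-accessors
#' @export
control_ids <- function(m) names(m$labels)[m$labels == "control"]

#' @rdname omics-accessors
#' @export
case_values <- function(m) m$values[, case_ids(m), drop = FALSE]

#' @rdname omics-accessors
#' @export
control_values <- function(m) m$values[, control_ids(m), drop = FALSE]

# Replace the value matrix, keeping labels aligned to the (possibly
# shrunken) column set.
.with_values <- function(m, values) {
  omics_matrix(values, m$labels)
}
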
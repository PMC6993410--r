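#' Read and write the pipeline's plain-text formats
#'
#' All tabular files are tab-separated with a header line. Matrices are
#' feature-by-sample, the first column holding feature IDs and the header
#' holding sample IDs. Labels files have columns `sample_id` and `group`
#' (`case`/`control`). Interaction catalogs are two-column (`tf`, `gene`),
#' drug catalogs two-column (`drug`, `gene`).
#'
#' @param path File path.
#' @param labels_path Path to the sample-label TSV matching the matrix.
#' @return `read_matrix_tsv` returns an [omics_matrix]; `read_labels` a
#'   named character vector; catalog readers return data frames.
#' @name methtdm-io
NULL

#' @rdname methtdm-io
#' @export
read_labels <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(d))) {
    stop("labels file must have columns 'sample_id' and 'group': ", path)
  }
  setNames(d$group, d$sample_id)
}

#' @rdname methtdm-io
#' @param labels Named character label vector (alternative to labels_path).
#' @export
read_matrix_tsv <- function(path, labels = NULL, labels_path = NULL) {
  if (is.null(labels)) {
    if (is.null(labels_path)) stop("supply 'labels' or 'labels_path'")
    labels <- read_labels(labels_path)
  }
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(d[, -1, drop = FALSE])
  rownames(v) <- as.character(d[[1]])
  storage.mode(v) <- "double"
  omics_matrix(v, labels)
}

#' @rdname methtdm-io
#' @param m An [omics_matrix] to serialize.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(feature_id = feature_ids(m), m$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname methtdm-io
#' @export
write_labels <- function(labels, path) {
  d <- data.frame(sample_id = names(labels), group = unname(labels))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname methtdm-io
#' @export
read_interaction_catalog <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("tf", "gene") %in% names(d))) {
    stop("interaction catalog must have columns 'tf' and 'gene': ", path)
  }
  d[, c("tf", "gene")]
}

#' @rdname methtdm-io
#' @export
read_drug_catalog <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("drug", "gene") %in% names(d))) {
    stop("drug catalog must have columns 'drug' and 'gene': ", path)
  }
  d[, c("drug", "gene")]
}

#' @rdname methtdm-io
#' @param x A data frame to serialize.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a GMT gene-set library
#'
#' One set per line: set name, description, then member genes, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @return `read_gmt`: a named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (gene sets).
#' @param descriptions Optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
  }
  if (is.null(descriptions)) descriptions <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
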
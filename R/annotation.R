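#' Fisher exact gene-set enrichment against a GMT library
#'
#' One-sided (greater) Fisher exact test per gene set, after
#' intersecting query and sets with the background universe; one
#' Benjamini-Hochberg family across all tested sets. Only sets with at
#' least one overlapping gene produce a record.
#'
#' @param query_genes Character vector of query genes (typically the
#'   union of TFs and genes in significant motifs). Must be contained in
#'   `background`.
#' @param gmt Named list of gene sets (see [read_gmt()]).
#' @param background Character vector: the gene universe (typically all
#'   genes present in the expression matrices).
#' @return Data frame `set_name`, `overlap_count`, `set_size`,
#'   `query_size`, `background_size`, `odds_ratio`, `p`, `q`, sorted by
#'   `p` ascending, ties by set name.
#' @export
fisher_enrichment <- function(query_genes, gmt, background) {
  query <- unique(as.character(query_genes))
  background <- unique(as.character(background))
  if (!length(query)) stop("empty query")
  if (!length(background)) stop("empty background")
  outside <- setdiff(query, background)
  if (length(outside)) {
    stop("query genes outside the background universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  N <- length(background)
  nq <- length(query)
  rows <- lapply(names(gmt), function(nm) {
    s <- intersect(unique(gmt[[nm]]), background)
    k <- length(intersect(query, s))
    if (k < 1) return(NULL)
    a <- k
    b <- nq - k
    cc <- length(s) - k
    d <- N - nq - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    odds <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
    data.frame(set_name = nm, overlap_count = a, set_size = length(s),
               query_size = nq, background_size = N, odds_ratio = odds,
               p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- data.frame(set_name = character(), overlap_count = integer(),
                      set_size = integer(), query_size = integer(),
                      background_size = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter enrichment records at a strict FDR threshold
#'
#' @param records Output of [fisher_enrichment()].
#' @param q_threshold Retention threshold; records with
#'   `q < q_threshold` (strict) are kept. Conventional values: 0.01 for
#'   GO libraries, 0.05 for pathway libraries.
#' @export
filter_enriched <- function(records, q_threshold) {
  out <- records[records$q < q_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drug-target repurposing network from significant motifs
#'
#' Restricts a drug-to-gene catalog to the TFs and genes appearing in
#' significant motifs, builds the simple bipartite drug-gene graph, and
#' ranks drugs by degree (ties by drug name) -- high-degree drugs are
#' the repurposing candidates.
#'
#' @param motifs Data frame of significant motifs (`tf`, `gene` columns).
#' @param drug_catalog Data frame `drug`, `gene`.
#' @return List with `network` (igraph, vertex attribute `role` in
#'   `drug`/`gene`) and `drug_degrees` (data frame `drug`, `degree`,
#'   sorted).
#' @export
build_drug_network <- function(motifs, drug_catalog) {
  if (!nrow(drug_catalog)) stop("empty drug catalog")
  motif_genes <- unique(c(motifs$tf, motifs$gene))
  edges <- unique(drug_catalog[drug_catalog$gene %in% motif_genes,
                               c("drug", "gene"), drop = FALSE])
  if (!nrow(edges)) {
    warning("no catalog gene appears in the motifs; empty drug network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(list(network = g,
                drug_degrees = data.frame(drug = character(),
                                          degree = integer(),
                                          stringsAsFactors = FALSE)))
  }
  if (length(intersect(edges$drug, edges$gene))) {
    stop("drug IDs collide with gene IDs")
  }
  drugs <- sort(unique(edges$drug))
  genes <- sort(unique(edges$gene))
  vdf <- rbind(data.frame(name = drugs, role = "drug", stringsAsFactors = FALSE),
               data.frame(name = genes, role = "gene", stringsAsFactors = FALSE))
  vdf$type <- vdf$role == "gene"
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vdf)
  deg <- igraph::degree(g, v = drugs)
  dd <- data.frame(drug = drugs, degree = as.integer(deg),
                   stringsAsFactors = FALSE)
  dd <- dd[order(-dd$degree, dd$drug), , drop = FALSE]
  rownames(dd) <- NULL
  list(network = g, drug_degrees = dd)
}

#' Top repurposing candidates by drug degree
#'
#' @param drug_net Output of [build_drug_network()].
#' @param n Number of drugs to report (default 10).
#' @export
top_drugs <- function(drug_net, n = 10) {
  utils::head(drug_net$drug_degrees, n)
}
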
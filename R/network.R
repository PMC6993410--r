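#' Build the bipartite methTDM network
#'
#' One node per distinct methylation site, one node per distinct TF-gene
#' pair (named `"TF|gene"`), and one undirected edge per significant
#' motif, carrying `delta`, `q`, and `pattern` attributes. The graph is
#' simple and bipartite by construction; the per-role tallies reported
#' alongside published networks (pairs, sites, TFs, genes, motifs) are
#' stored in the graph attribute `tally`.
#'
#' @param motifs Data frame of significant motifs with columns `site`,
#'   `tf`, `gene` and optionally `delta`, `q`, `pattern`.
#' @return An [igraph::igraph] with vertex attributes `role`
#'   (`"site"`/`"pair"`), `tf`, `gene`, and logical `type` (TRUE for
#'   pair nodes, for igraph bipartite support).
#' @export
build_network <- function(motifs) {
  key <- paste(motifs$site, motifs$tf, motifs$gene, sep = "\x1f")
  if (anyDuplicated(key)) stop("duplicate (site, tf, gene) motif keys")
  pair_name <- .pair_key(motifs$tf, motifs$gene)
  if (length(intersect(motifs$site, pair_name))) {
    stop("site IDs collide with pair node names")
  }
  sites <- unique(motifs$site)
  pairs <- unique(data.frame(name = pair_name, tf = motifs$tf,
                             gene = motifs$gene, stringsAsFactors = FALSE))
  vdf <- rbind(
    data.frame(name = sites, role = rep("site", length(sites)),
               tf = rep(NA_character_, length(sites)),
               gene = rep(NA_character_, length(sites)),
               stringsAsFactors = FALSE),
    data.frame(name = pairs$name, role = rep("pair", nrow(pairs)),
               tf = pairs$tf, gene = pairs$gene, stringsAsFactors = FALSE))
  vdf$type <- vdf$role == "pair"
  edf <- data.frame(from = motifs$site, to = pair_name,
                    stringsAsFactors = FALSE)
  if ("delta" %in% names(motifs)) edf$delta <- motifs$delta
  if ("q" %in% names(motifs)) edf$q <- motifs$q
  if ("pattern" %in% names(motifs)) edf$pattern <- motifs$pattern
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  g <- igraph::set_graph_attr(g, "tally", list(
    n_motifs = nrow(motifs),
    n_pairs = nrow(pairs),
    n_sites = length(sites),
    n_tfs = length(unique(motifs$tf)),
    n_genes = length(unique(motifs$gene))))
  g
}

.graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' Node degrees and the scale-free fit
#'
#' @param net An igraph network (e.g. from [build_network()]).
#' @return List with `degrees` (data frame `node`, `role`, `degree`),
#'   `fit` (the [log_log_fit()] over the full degree sequence), and
#'   `site_degrees` (the site-node rows only, the view used to ask how
#'   many pairs each methylation site influences).
#' @export
degree_table <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  deg <- igraph::degree(net)
  role <- igraph::vertex_attr(net, "role")
  if (is.null(role)) role <- rep(NA_character_, length(deg))
  d <- data.frame(node = igraph::V(net)$name, role = role,
                  degree = as.integer(deg), stringsAsFactors = FALSE)
  d <- d[order(-d$degree, d$node), , drop = FALSE]
  rownames(d) <- NULL
  list(degrees = d,
       fit = log_log_fit(d$degree),
       site_degrees = d[d$role == "site", , drop = FALSE])
}

# highest k-core of a graph: k and the density of the induced core
.highest_kcore <- function(g) {
  cor <- igraph::coreness(g)
  kmax <- max(cor)
  core <- igraph::induced_subgraph(g, which(cor >= kmax))
  list(k = kmax, density = .graph_density(core))
}

#' MCODE dense-module detection
#'
#' Reimplementation of the Molecular Complex Detection algorithm with
#' its documented defaults. (1) Vertex weighting: nodes with degree
#' below `degree_cutoff` score 0; otherwise the node's closed
#' neighborhood is reduced to its highest k-core and the weight is
#' `k x density` of that core. (2) Molecular complex prediction: seeds
#' are taken in decreasing weight order (ties by node name); from each
#' unseen seed, neighbors with weight >= `seed_weight x (1 -
#' node_score_cutoff)` are admitted breadth-first to `max_depth`, and
#' admitted nodes are never reused by later modules. (3)
#' Post-processing: modules lacking a `k_core` are discarded; `haircut`
#' removes singly-connected nodes (one pass). The module score is
#' `density x node count`; modules are ranked by score descending, ties
#' by the lexicographically smaller sorted node-name set. The `fluff`
#' option is accepted for interface compatibility but not implemented.
#'
#' @param net A simple undirected igraph.
#' @param degree_cutoff,node_score_cutoff,k_core,max_depth,haircut,fluff
#'   MCODE parameters (defaults 2, 0.2, 2, 100, TRUE, FALSE).
#' @return List of modules, each `list(nodes, score, rank)`, ranked;
#'   empty list when no module survives. The rank-1 module is the
#'   "core module".
#' @export
mcode_modules <- function(net, degree_cutoff = 2, node_score_cutoff = 0.2,
                          k_core = 2, max_depth = 100, haircut = TRUE,
                          fluff = FALSE) {
  if (isTRUE(fluff)) warning("MCODE 'fluff' post-processing is not implemented; ignored")
  g <- igraph::simplify(net)
  n <- igraph::vcount(g)
  if (n == 0) return(list())
  nm <- igraph::V(g)$name
  if (is.null(nm)) {
    nm <- as.character(seq_len(n))
    igraph::V(g)$name <- nm
  }
  deg <- igraph::degree(g)
  adj <- lapply(igraph::as_adj_list(g), as.integer)

  w <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < degree_cutoff) next
    hk <- .highest_kcore(igraph::induced_subgraph(g, c(v, adj[[v]])))
    w[v] <- hk$k * hk$density
  }

  seen <- logical(n)
  modules <- list()
  for (s in order(-w, nm)) {
    if (seen[s] || w[s] <= 0) next
    thr <- w[s] * (1 - node_score_cutoff)
    seen[s] <- TRUE
    members <- s
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (!seen[u] && w[u] >= thr) {
            seen[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < k_core) next
    if (haircut) {
      sub <- igraph::induced_subgraph(sub, which(igraph::degree(sub) >= 2))
    }
    if (igraph::vcount(sub) < 2) next
    modules[[length(modules) + 1L]] <- list(
      nodes = sort(igraph::V(sub)$name),
      score = .graph_density(sub) * igraph::vcount(sub))
  }
  if (!length(modules)) return(list())
  scores <- vapply(modules, `[[`, 0, "score")
  keys <- vapply(modules, function(m) paste(m$nodes, collapse = "\x1f"), "")
  ord <- order(-scores, keys)
  modules <- modules[ord]
  for (i in seq_along(modules)) modules[[i]]$rank <- i
  modules
}

#' Extract an ego subnetwork
#'
#' Induced subgraph on a node and all nodes within `radius` of it, edge
#' attributes preserved -- e.g. one methylation site together with every
#' TF-gene pair it influences.
#'
#' @param net An igraph network.
#' @param node_id Node name.
#' @param radius Neighborhood order (default 1).
#' @export
extract_ego <- function(net, node_id, radius = 1) {
  if (!node_id %in% igraph::V(net)$name) stop("unknown node: ", node_id)
  igraph::make_ego_graph(net, order = radius, nodes = node_id)[[1]]
}
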
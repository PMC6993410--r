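# Brute-force, definition-level oracles kept independent of the package
# implementations they check.

bf_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

bf_student_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  m1 <- sum(a) / n1; m2 <- sum(b) / n2
  sp2 <- (sum((a - m1)^2) + sum((b - m2)^2)) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df), df = df)
}

# exhaustive step-up scan: q_i = min over j with p_(j) >= p_i of p_(j)*m/j
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)  # position of p[i] in the sorted order
    cands <- vapply(seq.int(rank_i, m), function(j) p[ord[j]] * m / j, 0)
    q[i] <- min(1, min(cands))
  }
  q
}

# one-sided (greater) hypergeometric tail by direct summation over tables
bf_fisher_greater <- function(a, b, cc, d) {
  K <- a + b        # query size
  S <- a + cc       # set size
  N <- a + b + cc + d
  ks <- seq.int(a, min(K, S))
  sum(exp(lchoose(S, ks) + lchoose(N - S, K - ks) - lchoose(N, K)))
}

# BFS within a radius, on an igraph, by adjacency only
bf_ego_nodes <- function(g, start, radius) {
  nm <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g), function(v) nm[as.integer(v)])
  names(adj) <- nm
  seen <- start
  frontier <- start
  for (i in seq_len(radius)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

# small motif table with known composition, for pattern/network fixtures
fixture_motifs <- function(n = 10, seed = 42) {
  set.seed(seed)
  labs <- methTDM::pattern_labels
  data.frame(
    site = sprintf("cg%06d", sample(1:4, n, replace = TRUE)),
    tf = sprintf("TF%04d", sample(1:3, n, replace = TRUE)),
    gene = sprintf("G%05d", sample(1:4, n, replace = TRUE)),
    r_low = runif(n, -1, 1), r_high = runif(n, -1, 1),
    delta = runif(n, -2, 2), q = runif(n, 0, 0.05),
    pattern = sample(labs, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# dedupe on (site, tf, gene) so build_network accepts it
fixture_unique_motifs <- function(n = 10, seed = 42) {
  m <- fixture_motifs(n * 3, seed)
  m <- m[!duplicated(paste(m$site, m$tf, m$gene)), , drop = FALSE]
  head(m, n)
}

# config with k planted motifs, one row each, all (r_low, r_high) equal
uniform_motif_config <- function(k, r_low, r_high, n_case = 30,
                                 n_control = 18, seed = 1,
                                 scale = "log2", differential = TRUE) {
  motifs <- lapply(seq_len(k), function(i) {
    methTDM::planted_motif(i, i, i, r_low, r_high, differential)
  })
  methTDM::simulation_config(n_tf = k, n_gene = k, n_meth = k,
                             n_case = n_case, n_control = n_control,
                             planted_motifs = motifs, scale = scale,
                             seed = seed)
}
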
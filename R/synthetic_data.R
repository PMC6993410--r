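#' Planted methylation-TF-gene motif
#'
#' Ground-truth unit for the synthetic generator: a CpG site whose
#' methylation level modulates the correlation of one TF-gene pair.
#' `r_low` is the pair's correlation among case samples in the low-
#' methylation half, `r_high` in the high half.
#'
#' @param site,tf,gene 1-based integer indices into the site/TF/gene
#'   row spaces of the simulated matrices.
#' @param r_low,r_high Target Pearson correlations, strictly inside
#'   `(-1, 1)`.
#' @param differential Should the site's methylation differ in mean
#'   between case and control samples (default `TRUE`, so the site
#'   survives the differential-methylation screen)?
#' @return A `planted_motif` list.
#' @export
planted_motif <- function(site, tf, gene, r_low, r_high, differential = TRUE) {
  for (r in c(r_low, r_high)) {
    if (!is.finite(r) || abs(r) >= 1) {
      stop("requested correlation infeasible: |r| must be < 1, got ", r)
    }
  }
  structure(list(site = as.integer(site), tf = as.integer(tf),
                 gene = as.integer(gene), r_low = r_low, r_high = r_high,
                 differential = isTRUE(differential)),
            class = "planted_motif")
}

#' Simulation configuration
#'
#' Describes a synthetic case/control study. Defaults emulate the
#' placental design the pipeline targets: 30 case and 18 control
#' samples, methylation on the beta-value (0-1) scale with bimodal
#' planted sites, and expression generated as Gaussian on the log2
#' scale (written out as `2^x` when `scale = "raw"` so that the
#' preprocessing log2 step recovers the latent values exactly).
#'
#' @param n_tf,n_gene,n_meth Row counts of the three matrices.
#' @param n_case,n_control Sample counts per group.
#' @param planted_motifs List of [planted_motif()] objects. Motifs must
#'   reference in-range indices; to keep the generative model
#'   well-defined, no TF, gene, or site row may be claimed by two
#'   motifs.
#' @param n_null_pairs Number of truly uncorrelated decoy TF-gene pairs
#'   recorded in the ground truth (drawn from non-planted rows).
#' @param n_null_sites Number of non-planted sites recorded explicitly
#'   as truly non-differential nulls.
#' @param noise_sd Expression noise standard deviation on the log2 scale.
#' @param expr_mean Baseline expression mean on the log2 scale.
#' @param meth_shift Case-vs-control mean shift (beta scale) applied to
#'   differential sites.
#' @param meth_concentration Beta-distribution concentration (a + b) for
#'   methylation draws; larger is tighter.
#' @param scale `"raw"` writes expression as `2^latent` (pipeline input),
#'   `"log2"` keeps the latent Gaussian values.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_tf, n_gene, n_meth,
                              n_case = 30, n_control = 18,
                              planted_motifs = list(),
                              n_null_pairs = 0, n_null_sites = 0,
                              noise_sd = 1, expr_mean = 8,
                              meth_shift = 0.3, meth_concentration = 30,
                              scale = c("raw", "log2"), seed = 1) {
  scale <- match.arg(scale)
  cfg <- list(n_tf = as.integer(n_tf), n_gene = as.integer(n_gene),
              n_meth = as.integer(n_meth), n_case = as.integer(n_case),
              n_control = as.integer(n_control),
              planted_motifs = planted_motifs,
              n_null_pairs = as.integer(n_null_pairs),
              n_null_sites = as.integer(n_null_sites),
              noise_sd = noise_sd, expr_mean = expr_mean,
              meth_shift = meth_shift,
              meth_concentration = meth_concentration,
              scale = scale, seed = as.integer(seed))
  .validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_config <- function(cfg) {
  if (cfg$n_case < 5 || cfg$n_control < 5) {
    stop("need at least 5 case and 5 control samples")
  }
  if (any(c(cfg$n_tf, cfg$n_gene, cfg$n_meth) < 1)) {
    stop("feature counts must be positive")
  }
  if (cfg$noise_sd <= 0) stop("'noise_sd' must be positive")
  pm <- cfg$planted_motifs
  if (length(pm)) {
    if (!all(vapply(pm, inherits, TRUE, "planted_motif"))) {
      stop("'planted_motifs' must be a list of planted_motif objects")
    }
    sites <- vapply(pm, `[[`, 1L, "site")
    tfs <- vapply(pm, `[[`, 1L, "tf")
    genes <- vapply(pm, `[[`, 1L, "gene")
    if (any(sites < 1 | sites > cfg$n_meth) ||
        any(tfs < 1 | tfs > cfg$n_tf) ||
        any(genes < 1 | genes > cfg$n_gene)) {
      stop("planted motif references an out-of-range TF/gene/site index")
    }
    if (anyDuplicated(sites) || anyDuplicated(tfs) || anyDuplicated(genes)) {
      stop("each TF, gene, and site row may be claimed by at most one planted motif")
    }
  }
  n_planted_sites <- length(unique(vapply(pm, `[[`, 1L, "site")))
  if (cfg$n_null_sites > cfg$n_meth - n_planted_sites) {
    stop("'n_null_sites' exceeds the number of non-planted sites")
  }
  invisible(cfg)
}

.site_id <- function(i) sprintf("cg%06d", i)
.tf_id <- function(i) sprintf("TF%04d", i)
.gene_id <- function(i) sprintf("G%05d", i)

# beta draw parameterized by mean and concentration
.rbeta_mu <- function(n, mu, kappa) stats::rbeta(n, mu * kappa, (1 - mu) * kappa)

#' Simulate sample-matched TF, gene, and methylation profiles
#'
#' Deterministic given `config$seed`. For every planted motif, the
#' site's case methylation is drawn from an equal-weight bimodal Beta
#' mixture (means 0.2 and 0.8), case samples are split at the per-site
#' median into a low and a high half, and the motif's (TF, gene)
#' expression pair is drawn from a bivariate normal with correlation
#' `r_low` (low half) or `r_high` (high half). The median split makes
#' the analysis stage's 40% tails strict subsets of the generative
#' strata, so planted contrasts survive the stricter split. Null TFs,
#' genes, and sites are independent noise; differential sites receive a
#' case-vs-control mean shift of `meth_shift` on the beta scale.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `tf`, `gene`, `meth` (each an
#'   [omics_matrix] over the same ordered samples) and `truth`, a
#'   `ground_truth` list recording every planted motif with its true
#'   `(r_low, r_high)`, its true pattern label, the truly differential
#'   sites, the truly correlated pairs, explicit null pairs/sites, and
#'   the full ID universes.
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .validate_config(config)
  set.seed(config$seed)
  nc <- config$n_case
  nk <- config$n_control
  kappa <- config$meth_concentration
  case_ids <- sprintf("case_%03d", seq_len(nc))
  ctrl_ids <- sprintf("ctrl_%03d", seq_len(nk))
  samples <- c(case_ids, ctrl_ids)
  labels <- setNames(c(rep("case", nc), rep("control", nk)), samples)
  site_ids <- .site_id(seq_len(config$n_meth))
  tf_ids <- .tf_id(seq_len(config$n_tf))
  gene_ids <- .gene_id(seq_len(config$n_gene))

  pm <- config$planted_motifs
  motif_site <- vapply(pm, `[[`, 1L, "site")

  # methylation: site by site, cases then controls
  meth <- matrix(NA_real_, config$n_meth, nc + nk,
                 dimnames = list(site_ids, samples))
  mu_ctrl <- min(0.95, 0.5 + config$meth_shift)
  for (i in seq_len(config$n_meth)) {
    j <- match(i, motif_site)
    if (!is.na(j)) {
      comp <- stats::rbinom(nc, 1, 0.5)
      lo <- .rbeta_mu(nc, 0.2, kappa)
      hi <- .rbeta_mu(nc, 0.8, kappa)
      case_v <- ifelse(comp == 1, hi, lo)
      if (pm[[j]]$differential) {
        ctrl_v <- .rbeta_mu(nk, mu_ctrl, kappa)
      } else {
        compc <- stats::rbinom(nk, 1, 0.5)
        ctrl_v <- ifelse(compc == 1, .rbeta_mu(nk, 0.8, kappa),
                         .rbeta_mu(nk, 0.2, kappa))
      }
    } else {
      case_v <- .rbeta_mu(nc, 0.5, kappa)
      ctrl_v <- .rbeta_mu(nk, 0.5, kappa)
    }
    meth[i, ] <- c(case_v, ctrl_v)
  }

  # expression baselines (latent log2 scale)
  tf_v <- matrix(stats::rnorm(config$n_tf * (nc + nk), config$expr_mean,
                              config$noise_sd),
                 config$n_tf, nc + nk, dimnames = list(tf_ids, samples))
  gene_v <- matrix(stats::rnorm(config$n_gene * (nc + nk), config$expr_mean,
                                config$noise_sd),
                   config$n_gene, nc + nk, dimnames = list(gene_ids, samples))

  # overwrite case columns of planted motif rows with correlated draws
  half <- floor(nc / 2)
  for (mo in pm) {
    v <- meth[mo$site, case_ids]
    ord <- order(v, case_ids)
    strata <- list(low = ord[seq_len(half)],
                   high = ord[seq.int(half + 1L, nc)])
    rs <- c(low = mo$r_low, high = mo$r_high)
    for (s in names(strata)) {
      idx <- strata[[s]]
      r <- rs[[s]]
      z1 <- stats::rnorm(length(idx))
      z2 <- stats::rnorm(length(idx))
      tf_v[mo$tf, case_ids[idx]] <- config$expr_mean + config$noise_sd * z1
      gene_v[mo$gene, case_ids[idx]] <-
        config$expr_mean + config$noise_sd * (r * z1 + sqrt(1 - r^2) * z2)
    }
  }

  if (config$scale == "raw") {
    tf_v <- 2^tf_v
    gene_v <- 2^gene_v
  }

  # ground truth
  motif_df <- if (length(pm)) {
    data.frame(site = .site_id(vapply(pm, `[[`, 1L, "site")),
               tf = .tf_id(vapply(pm, `[[`, 1L, "tf")),
               gene = .gene_id(vapply(pm, `[[`, 1L, "gene")),
               r_low = vapply(pm, `[[`, 1, "r_low"),
               r_high = vapply(pm, `[[`, 1, "r_high"),
               differential = vapply(pm, `[[`, TRUE, "differential"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(site = character(), tf = character(), gene = character(),
               r_low = numeric(), r_high = numeric(),
               differential = logical(), stringsAsFactors = FALSE)
  }
  motif_df$pattern <- classify_pattern(motif_df$r_low, motif_df$r_high)

  null_tfs <- setdiff(tf_ids, motif_df$tf)
  null_genes <- setdiff(gene_ids, motif_df$gene)
  null_sites_all <- setdiff(site_ids, motif_df$site)
  null_pairs <- if (config$n_null_pairs > 0) {
    if (!length(null_tfs) || !length(null_genes)) {
      stop("no non-planted rows available for null pairs")
    }
    data.frame(
      tf = sample(null_tfs, config$n_null_pairs, replace = TRUE),
      gene = sample(null_genes, config$n_null_pairs, replace = TRUE),
      stringsAsFactors = FALSE)
  } else {
    data.frame(tf = character(), gene = character(), stringsAsFactors = FALSE)
  }
  null_pairs <- unique(null_pairs)

  truth <- structure(list(
    motifs = motif_df,
    diff_sites = motif_df$site[motif_df$differential],
    corr_pairs = motif_df[, c("tf", "gene")],
    null_pairs = null_pairs,
    null_sites = utils::head(null_sites_all, config$n_null_sites),
    tf_ids = tf_ids, gene_ids = gene_ids, site_ids = site_ids
  ), class = "ground_truth")

  list(tf = omics_matrix(tf_v, labels),
       gene = omics_matrix(gene_v, labels),
       meth = omics_matrix(meth, labels),
       truth = truth)
}

#' Simulate a TF-to-gene interaction catalog
#'
#' Stand-in for a curated TF-target catalog: every planted pair plus
#' `n_extra` random decoy pairs drawn from the simulated ID universes,
#' with duplicates redrawn so the catalog has exactly
#' `nrow(planted) + n_extra` unique rows.
#'
#' @param truth `ground_truth` from [simulate_profiles()].
#' @param n_extra Number of decoy pairs.
#' @param seed Integer RNG seed.
#' @return Data frame with columns `tf`, `gene`.
#' @export
simulate_interaction_catalog <- function(truth, n_extra = 0, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(as.integer(seed))
  cat <- unique(truth$corr_pairs)
  key <- function(d) paste(d$tf, d$gene, sep = "\x1f")
  seen <- key(cat)
  n_extra <- as.integer(n_extra)
  available <- length(truth$tf_ids) * length(truth$gene_ids) - nrow(cat)
  if (n_extra > available) {
    stop("requested ", n_extra, " decoy pairs but only ", available,
         " non-planted pairs exist")
  }
  guard <- 0L
  while (n_extra > 0) {
    cand <- data.frame(tf = sample(truth$tf_ids, n_extra, replace = TRUE),
                       gene = sample(truth$gene_ids, n_extra, replace = TRUE),
                       stringsAsFactors = FALSE)
    cand <- cand[!duplicated(key(cand)) & !key(cand) %in% seen, , drop = FALSE]
    if (nrow(cand)) {
      cat <- rbind(cat, cand)
      seen <- c(seen, key(cand))
      n_extra <- n_extra - nrow(cand)
    }
    guard <- guard + 1L
    if (guard > 1000L) stop("could not draw enough unique decoy pairs")
  }
  rownames(cat) <- NULL
  cat
}

#' Simulate annotation inputs: a GMT library and a drug-target catalog
#'
#' Builds gene sets and a drug catalog around a query gene list so that
#' downstream enrichment and drug-network behavior is known by
#' construction: one designated set (`SET_ENRICHED`) consists of query
#' genes only, and one designated hub drug (`DRUG_HUB`) targets
#' `hub_targets` of the query genes, giving it that exact degree in the
#' drug network. Remaining sets and drugs are random draws from the
#' background.
#'
#' @param genes Nonempty character vector of query genes (e.g. the TFs
#'   and genes of planted motifs).
#' @param seed Integer RNG seed.
#' @param background Gene universe to draw decoy set/drug members from
#'   (defaults to `genes`).
#' @param n_sets Total number of gene sets (>= 1).
#' @param set_size Size of the designated enriched set (capped at
#'   `length(genes)`).
#' @param n_drugs Total number of drugs; 0 gives a valid empty catalog.
#' @param hub_targets Degree of the designated hub drug.
#' @param gmt_path,drug_path Optional output paths; written when given.
#' @return List with `gene_sets` (named list, `descriptions` attribute),
#'   and `drug_catalog` (data frame `drug`, `gene`).
#' @export
simulate_annotation_files <- function(genes, seed = 1, background = genes,
                                      n_sets = 5, set_size = 10,
                                      n_drugs = 20,
                                      hub_targets = min(13L, length(genes)),
                                      gmt_path = NULL, drug_path = NULL) {
  if (!length(genes)) stop("'genes' must be nonempty")
  set.seed(as.integer(seed))
  genes <- unique(as.character(genes))
  background <- unique(c(as.character(background), genes))
  sets <- list(SET_ENRICHED = utils::head(genes, max(1, min(set_size, length(genes)))))
  if (n_sets > 1) {
    for (i in seq_len(n_sets - 1)) {
      sz <- min(length(background), max(3, set_size))
      sets[[sprintf("SET_%03d", i)]] <- sort(sample(background, sz))
    }
  }
  descriptions <- setNames(rep("synthetic gene set", length(sets)), names(sets))

  drug_catalog <- data.frame(drug = character(), gene = character(),
                             stringsAsFactors = FALSE)
  if (n_drugs > 0) {
    hub_targets <- min(hub_targets, length(genes))
    if (hub_targets > 0) {
      drug_catalog <- data.frame(drug = "DRUG_HUB",
                                 gene = utils::head(genes, hub_targets),
                                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_drugs - 1)) {
      k <- sample(1:3, 1)
      drug_catalog <- rbind(drug_catalog,
                            data.frame(drug = sprintf("DRUG_%03d", i),
                                       gene = sample(background, k),
                                       stringsAsFactors = FALSE))
    }
    drug_catalog <- unique(drug_catalog)
    rownames(drug_catalog) <- NULL
  }

  if (!is.null(gmt_path)) write_gmt(sets, gmt_path, descriptions)
  if (!is.null(drug_path)) write_tsv(drug_catalog, drug_path)
  attr(sets, "descriptions") <- descriptions
  list(gene_sets = sets, drug_catalog = drug_catalog)
}

#' Serialize ground truth as JSON
#' @param truth `ground_truth` object.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
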
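---
title: "Discovering methylation-mediated transcriptional dysregulation motifs"
author: "methTDM package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering methylation-mediated transcriptional dysregulation motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methTDM)
```

## The question and the model

A transcription factor (TF) regulates a target gene; DNA methylation near a
binding site can weaken, strengthen, or invert that regulation. A
*methylation-mediated transcriptional dysregulation motif* (methTDM) is a
triple (CpG site, TF, gene) in which the TF–gene correlation among case
samples depends on the site's methylation level. The package detects such
motifs in a case/control design with three sample-matched matrices — TF
expression, gene expression, and methylation beta values — plus a curated
TF→target catalog.

The procedure, stage by stage:

1. **Preprocessing.** Features that are zero in every sample are dropped;
   remaining zeros are imputed with the global minimum *nonzero* value
   (reading "minimum value of all samples" literally would impute 0 with 0,
   a no-op, so the nonzero minimum is the only reading that changes the
   data); values are log2-transformed; multi-probe features are averaged
   per gene symbol. log2 is strictly monotone, so the quantile
   stratification below is unaffected by whether methylation is
   transformed; a `log2 = FALSE` flag keeps beta values as such.
2. **Candidate universe.** A TF–gene pair is case-specific when the Pearson
   correlation of its expression *over case samples only* satisfies
   |r| > 0.25 (strict). A site is differential when a pooled-variance
   two-sample t test, Benjamini–Hochberg-adjusted across all testable
   sites, gives q < 0.05 (strict).
3. **Stratified correlation contrast.** For each retained site, case
   samples are ranked by methylation (ties broken by sample ID, so the
   split is deterministic); the bottom and top floor(0.4 n) samples form
   the low and high strata — 12 vs 12 at n = 30. For each (site, pair)
   combination, Δ = r_high − r_low; |Δ| > 0.7 (strict) defines a candidate
   motif. With 30 cases, 0.4·30 = 12 is exact; for other n, floor() is
   used.
4. **Permutation significance.** The null is "methylation does not modulate
   the pair": each permutation shuffles the assignment between the site's
   methylation values and the case samples, leaving the TF–gene pairing
   intact, then re-stratifies and recomputes |Δ|. The add-one estimator
   p = (1 + #{|Δ*| ≥ |Δ|}) / (B + 1) can never be 0; B = 1000 by default.
   One global BH family across all candidates; q < 0.05 (strict) defines a
   significant motif. Per-motif RNG seeds derive from
   (master seed, site, tf, gene) via a stable string hash, so results do
   not depend on iteration order.
5. **Pattern classification.** The low-methylation stratum is the baseline:
   r_low < 0 is inhibition, r_low > 0 activation. Methylation then
   relaxes (same sign, |r_high| < |r_low|), intensifies (same sign,
   |r_high| > |r_low|), or reverses (opposite sign) the action — six
   labels. Exact magnitude ties resolve to the relax label. A baseline
   direction is callable only when |r_low| ≥ τ = 0.25 (reusing the
   interaction-screen threshold); other motifs are reported as
   unclassifiable and excluded from summaries. An alternative baseline
   (the all-case correlation) is available behind
   `classify_motifs(baseline = "r_case")`.
6. **Network and modules.** Significant motifs form a bipartite graph:
   site nodes and TF-gene-pair nodes, one edge per motif. Degrees are
   summarized and fitted by ordinary least squares of log10(count) on
   log10(degree) — the scale-free convention of network viewers; raw
   counts, no binning, no CCDF. Dense modules come from a reimplementation
   of MCODE (defaults: degree cutoff 2, node score cutoff 0.2, k-core 2,
   max depth 100, haircut on, fluff parsed but unimplemented); the
   rank-1 module is the core module. Graph density is 2E/(N(N−1)), 0 for a
   single node.
7. **Annotation.** Enrichment of the motif TFs+genes against GMT libraries
   by one-sided Fisher exact tests with BH (replacing a web service's
   combined score, which is out of scope); query universe = TFs ∪ genes of
   significant motifs; background defaults to all genes in the expression
   matrices and is overridable. A drug→gene catalog restricted to motif
   genes yields a bipartite drug network; drugs ranked by degree are the
   repurposing candidates.

## Tunable parameters

| parameter | default | units / scale | why |
|---|---|---|---|
| `r_threshold` | 0.25 | Pearson r | case-specific interaction screen, strict |
| `q_threshold` (sites, motifs) | 0.05 | BH FDR | strict, one global family each |
| `fraction` | 0.4 | of case samples | top/bottom methylation tails, floor() |
| `delta_threshold` | 0.7 | correlation difference | candidate motif screen, strict |
| `n_perm` | 1000 | permutations | add-one p floor ≈ 0.001 |
| `tau` | 0.25 | Pearson r | minimum \|r_low\| for a direction call |
| enrichment FDR | 0.01 / 0.05 | BH q | GO-like vs pathway-like libraries |
| MCODE | 2 / 0.2 / 2 / 100 | — | the plugin's documented defaults |

## The synthetic-data generator

`simulate_profiles()` emulates the targeted study design: 30 case and 18
control samples by default. For each planted motif, the site's case
methylation is an equal-weight bimodal Beta mixture (means 0.2 and 0.8,
concentration κ = 30), so the analysis tails are well separated; case
samples are split at the per-site *median* and the motif's (TF, gene) pair
is drawn from a bivariate normal with correlation r_low below the median
and r_high above it. The median split makes the analysis's 40% tails strict
subsets of the generative strata, so a planted contrast survives the
stricter split. Differential sites shift the control mean by 0.3 on the
beta scale (control mean 0.8 vs case mixture mean 0.5) — comfortably
detectable at n = 30/18 with κ = 30 noise. Expression is Gaussian on the
log2 scale (mean 8, sd 1) and written as `2^latent` when `scale = "raw"`,
so the preprocessing log2 step recovers the latent values exactly; planted
correlations are therefore stated on the analysis (log2) scale. Null TFs,
genes, and sites are independent noise. Each TF, gene, and site row may be
claimed by at most one planted motif — sharing a row across motifs would
make the generative model ill-defined — which is stricter than requiring
unique triples.

What the generator does **not** emulate: genome coordinates and CpG-island
structure, array-probe chemistry, batch effects, heteroscedastic
expression noise, correlated null features, and the joint
methylation–expression distribution of real placental tissue (the
mixture/bivariate-normal model is this package's own assumption). A green
recovery test therefore establishes that the pipeline finds what its model
class plants, at the stated sizes and noise — not that the biological
assumptions hold.

## Numerical choices

- All retention thresholds are strict inequalities, read literally from
  their definitions; boundary cases (r = 0.25, |Δ| = 0.7, q = 0.05/0.01)
  are dropped.
- Degenerate inputs are never silent: zero-variance correlation input is an
  error; untestable catalog pairs, sites, and motifs are excluded into
  skipped/untestable reports with reasons. Degenerate permutation
  replicates are redrawn with a cap of 10·B draws.
- Ties: stratification breaks methylation ties by sample ID; MCODE breaks
  seed ties by node name and module-rank ties by the lexicographically
  smaller node set; output tables sort by (q, −|Δ|, site, tf, gene).
- The `simulate` CLI consumes a JSON configuration (no YAML parser is
  available in the dependency set).

## Known limitations

- **The candidate screen and the permutation test share a statistic.**
  Candidates are selected at |Δ| > 0.7 and then permutation-tested on |Δ|;
  a null motif that clears the screen by chance necessarily has an
  observed |Δ| in the tail of its own permutation null, hence a small p,
  and BH retains it. The realized false-discovery proportion among
  significant motifs therefore exceeds the nominal 0.05 — in the package's
  planted-motif recovery simulations (50 strong reverse plants among 450
  moderately correlated, non-modulated nulls at n = 30) sensitivity is
  ≈ 1 but the empirical FDR is ≈ 0.15. The permutation p-values themselves
  are well calibrated (uniform under the global null); the inflation is
  purely a selection effect of the published two-stage design. Users who
  need stringent error control should treat q as a ranking score or apply
  the permutation to all tested combinations (`delta_threshold = 0`).
- Motifs whose pair reverses sign (r_low ≈ −r_high) have an all-case
  correlation near 0 and are removed by the |r| > 0.25 interaction screen
  before detection — the full pipeline is structurally blind to
  symmetric reverse motifs, even though the detection stage finds them
  when given the pair directly.
- Intensify patterns with a callable baseline (|r_low| ≥ 0.4) can never
  exceed |Δ| > 0.7 (the gap is capped at 1 − |r_low| < 0.6), so detected
  intensify motifs are rare and arise only near the τ boundary — consistent
  with such patterns being reported as rare.
- MCODE's fluff option is accepted but not implemented; module membership
  is disjoint by construction.
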
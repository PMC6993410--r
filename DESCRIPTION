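Package: methTDM
Title: Discovery of Methylation-Mediated Transcriptional Dysregulation Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies methylation-mediated transcriptional dysregulation
    motifs (methTDMs) from sample-matched transcription-factor expression,
    gene expression, and DNA-methylation matrices in a case/control design.
    Case samples are stratified into low- and high-methylation tails for
    each differential CpG site, TF-gene Pearson correlations are compared
    between strata, and motifs with large correlation shifts are assessed
    by label permutation with Benjamini-Hochberg FDR control. Significant
    motifs are classified into six regulation patterns
    (relax/intensify/reverse x activation/inhibition), assembled into a
    bipartite site-pair network with MCODE dense-module detection, and
    annotated by gene-set enrichment and a drug-target repurposing network.
    Includes a synthetic-data generator with planted motifs of known
    pattern so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
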
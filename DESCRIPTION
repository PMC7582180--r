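Package: methmir
Title: Integrated Differential DNA Methylation and miRNA Network Analysis for Sorted T Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-group differential DNA methylation analysis of M-values with
    empirical-Bayes variance moderation and Benjamini-Hochberg control,
    distance-rule collapse of probes into differentially methylated regions,
    differential miRNA expression, an integrated miRNA-CpG Spearman
    correlation network with Leiden community detection and antagonistic
    community identification, CpG-to-mRNA coupling analysis, comparative-Ct
    qPCR statistics, and gene-set over-representation analysis. Includes a
    synthetic-data generator with planted ground truth for recovery
    benchmarking, and bundled reference tables of differentially methylated
    probes and regions in skin-homing CD4+CLA+ T cells from adult atopic
    dermatitis patients versus healthy controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
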
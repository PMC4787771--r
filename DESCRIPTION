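Package: nestdecomp
Title: Nested Variance Decomposition for Paired Microarray and RNA-Seq
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-gene nested-ANOVA variance decomposition of balanced
    two-condition expression experiments into condition, biological,
    preparation and chip/lane components, on both a Gaussian
    adjusted-R2 scale and a Poisson deviance-R2 scale for counts.
    Includes intensity-quantile smoothing with confidence bands,
    binned cross-platform comparison tests, replicate pooling and
    between-sample normalization, weighted linear models with
    empirical-Bayes moderated t-statistics and q-value FDR estimation,
    rolling-window cross-platform fold-change concordance, simulated
    qPCR validation of low-intensity discordant genes, Wilcoxon
    rank-sum gene-set enrichment with intensity-bin diagnostics, and a
    paired-platform synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    limma,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
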
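Package: crdgrn
Title: Enhancer-Centric Gene Regulatory Networks from Chromatin
    Regulatory Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds disease-specific, enhancer-mediated gene regulatory
    networks from cohort-level H3K27ac ChIP-Seq peak counts, RNA-Seq gene
    counts, CTCF/cohesin ChIA-PET loops and transcription-factor motif
    annotations.  Provides median-of-ratios normalization and per-feature
    differential analysis with covariates, diffTF-style differential TF
    activity with a permutation null, chromatin regulatory domain (CRD)
    calling from anchor-pair correlations, within-CRD enhancer-to-gene
    linking, empirical-FDR TF-to-enhancer linking, network assembly with
    consistency diagnostics, Fisher's-exact set enrichment, and a seeded
    negative-binomial multi-omic cohort simulator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
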
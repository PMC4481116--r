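Package: screenprint
Title: Functional Fingerprinting of Cell Populations from Arrayed RNAi
    Viability Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for arrayed loss-of-function viability
    screens in 384-well plates: plate-level normalization (control-based
    relative viability, multiplicative scaling with log transform,
    robust per-experiment variance adjustment, replicate summarization,
    plate-mean z-scores), screen quality control (Z'-factor, replicate
    profile correlations, quantile-quantile tail analysis), fold-change
    hit calling, and functional fingerprinting of cell populations:
    gene-by-sample log2 viability matrices, pairwise Pearson
    correlation, bi-dimensional hierarchical clustering with optimal
    leaf ordering, and small-n differential gene panels with post-hoc
    power via the noncentral t distribution. Includes a calibrated
    generative simulator for multi-donor kinome viability screens with
    planted effects and full ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
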
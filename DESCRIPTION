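Package: exprstate
Title: Global Gene Expression System State Scoring and Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the global state of a gene expression system as the
    first principal component score (PCA1) of a z-scored expression matrix,
    one value per sample, and validates that score with a feature-subsampling
    concordance protocol on non-overlapping probe groups. Includes
    microarray-style preprocessing (present-call filtering, probe-to-gene
    summarization, log2 fold changes), system-level diagnostics (correlation
    network connectivity, Euclidean distance from the lowest-state
    transcriptome, cross-region fold-change concordance), normality-gated
    state-behavior association, and a latent-state synthetic study generator
    emulating a two-region, two-arm antidepressant treatment design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
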
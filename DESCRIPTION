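Package: switchscan
Title: Dynamic Pattern Analysis of Temporal Transcription-Factor Binding
    from Promoter Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects transcription-factor binding peaks on promoter
    tiling-array time courses with a cutoff-scan sliding-window caller and
    a permutation-based empirical false discovery rate, annotates peaks to
    genes by distance to the transcription start site, discretizes binding
    across time points into binary patterns with replicate consensus,
    pairs patterns into binding/unbinding switches, and couples binding
    dynamics to differential gene expression. Includes a synthetic-data
    generator with known ground truth for every stage, a hypergeometric
    over-representation test for per-switch gene lists, and an end-to-end
    pipeline driven by a single YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
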
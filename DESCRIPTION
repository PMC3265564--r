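Package: cobindcode
Title: Combinatorial Regulatory Codes from ChIP-Seq Co-Binding and Motif
    Scanning
Version: 0.1.0
Authors@R:
    person("Gene", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers combinatorial regulatory codes in embryonic stem
    (ES) cells: combinations of ChIP-seq-profiled "main" transcription
    factors and motif-predicted cofactors whose co-binding near genes
    discriminates ES-up-regulated from ES-down-regulated genes.  The
    pipeline computes TF-gene association scores with exponential
    distance decay, clusters genes by binding pattern (k-means, k = 5),
    builds merged peak neighborhoods, scans them with position weight
    matrices against a first-order Markov background calibrated on
    matched control sequences, scores gene-feature associations,
    screens features by Wilcoxon rank-sum and two-sample proportion
    tests under Benjamini-Hochberg FDR control, selects features with a
    kernel-density naive Bayes classifier under ten-fold
    cross-validation, and predicts and validates regulatory targets.  A
    synthetic-data generator with a ground-truth manifest makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
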
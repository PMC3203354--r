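Package: sigsearch
Title: Phenotype-Naive Signature Association Search Across Expression Compendia
Version: 0.1.0
Authors@R:
    person("sigsearch", "developers", email = "sigsearch@example.org",
           role = c("aut", "cre"))
Description: Scores every sample in a compendium of gene expression datasets
    for coordinate differential expression of an up/down query gene signature
    using a per-sample Wilcoxon rank-sum statistic (the signature association,
    or SA, score), then ranks datasets by enrichment of signature-associated
    samples with two-sample Kolmogorov-Smirnov and exact 2x3 Fisher
    (Freeman-Halton) tests under Benjamini-Hochberg FDR control. Includes
    within-dataset per-platform z-score normalization, a synthetic-compendium
    generator with planted coordinate effects, per-gene shuffling and
    sample-subsetting protocols, ROC utilities, and power/Type-I sweep
    machinery, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
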
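Package: endoref
Title: Selection and Validation of Endogenous Normalizer miRNAs for RT-qPCR
Version: 0.1.0
Authors@R:
    person("endoref", "developers", email = "endoref@example.org", role = c("aut", "cre"))
Description: Tools for identifying optimal endogenous control (reference)
    miRNAs for RT-qPCR normalization. Implements four expression-stability
    estimators (NormFinder-style two-way model residuals, geNorm M values
    with stepwise exclusion, BestKeeper descriptive statistics, and the
    comparative delta-Ct method) together with a comprehensive
    geometric-mean-of-ranks score, an iterative greedy algorithm that builds
    reference sets of increasing size to decide how many normalizers to
    combine, standard-curve amplification-efficiency analysis, multi-reference
    delta-delta-Ct relative quantification with significance testing, a
    miRNA sequence-similarity screen for cross-hybridization risk, and
    seeded synthetic-data generators (Cq tables, negative-binomial count
    matrices, dilution series) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
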
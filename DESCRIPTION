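Package: encodeGP
Title: Genotype Encodings for Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the numeric encoding of biallelic SNP
    genotypes affects quantitative trait prediction. Implements ordinal,
    correlation-flipped ordinal, target-based, and two hybrid encodings that
    combine per-marker flexibility with preservation of genotype-category
    order, together with their extension to pairwise epistasis as 3x3
    per-pair grids. Provides ridge-regression BLUP (rrBLUP) with
    REML-estimated shrinkage via spectral decomposition, a support vector
    regression wrapper, a leakage-safe k-fold cross-validation harness,
    encoding diagnostics (top-k marker-trait correlation and within-group
    sample distance), and a synthetic genotype/phenotype simulator with
    additive, dominance and epistatic architectures under Hardy-Weinberg
    proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
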
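Package: nitroot
Title: Genotype-by-Nitrate Factorial Transcriptomics and Nitrogen
    Acquisition Efficiency Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for two-genotype by two-nitrate-level plant
    experiments of the kind used to characterise highly branched root
    mutants. Implements gene-wise two-way factorial ANOVA on normalized
    log2 expression matrices with a trimmed pooled (global) residual
    variance, chi-square contrast tests for genotype, nitrate and
    interaction effects, Bonferroni family-wise error control and
    Venn-style differential-expression classification; ecophysiological
    nitrogen-acquisition efficiency metrics (mean lateral root length,
    total plant nitrogen, N-uptake rate per unit root surface area,
    leaf area produced per unit nitrogen) from longitudinal destructive
    phenotyping, with Fisher least-significant-difference letter
    groupings; and relative-standard-curve (delta-CT) qPCR
    quantification with dual reference-gene normalization. Ships
    synthetic-data generators with known ground truth for all three
    data types, so every stage can be validated against planted effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
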
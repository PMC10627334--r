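Package: wheatlma
Title: Trait-to-Biomarker Discovery for Large Label-Free LC-MS Peptide Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements an end-to-end biomarker discovery workflow for large
    label-free LC-MS peptide-cluster intensity matrices phenotyped with a single
    quantitative trait, motivated by the wheat late-maturity alpha-amylase (LMA)
    problem. Provides a seeded synthetic cohort generator with planted
    trait-associated peptides and injected technical biases; a three-step
    normalization cascade (flour weight, internal standard, QC-anchored
    injection-order drift); quantification and removal of technical-factor
    effects via ANOVA simultaneous component analysis (ASCA) with permutation
    testing and per-feature fixed-effect residualization; trait transformation,
    unbiased subsampling, and PLS-regression imputation of missing trait values;
    multivariate (NIPALS PLS with VIP scores, batch SOM, correlation-distance
    k-means, divisive hierarchical clustering) and bivariate (correlation,
    per-feature regression with Benjamini-Hochberg q-values) screens against the
    trait inserted as a pseudo-feature row; union biomarker selection; binned
    trait profiling with two-group testing; and ppm/RT-tolerance matching of
    quantitative MS1 clusters to MS2 identification clusters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
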
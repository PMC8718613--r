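Package: aminonet
Title: Correlation-Network Analysis of Amino Acid Metabolomic Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential correlation-network analysis for targeted amino acid
    metabolomics. Builds per-group Pearson correlation networks over a
    17-analyte cerebellar panel (16 free amino acids plus 2-oxoglutarate
    dehydrogenase complex activity), quantifies metabolic interdependence by
    summarized and mean absolute correlation coefficients and signed counts of
    significant correlations, and tracks stress-induced network reorganization
    through hub-centered algebraic sums of signed correlations. Group
    comparisons use an exact Wilcoxon signed-rank test, two-way Type II ANOVA
    and Tukey-Kramer post-hoc contrasts. Includes a multivariate synthetic
    cohort generator with positive-definite target-correlation repair for
    parameter-recovery testing, and heart-rate-variability endpoints (mean R-R
    interval, RMSSD, Baevsky stress index) computed from R-R interval series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
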
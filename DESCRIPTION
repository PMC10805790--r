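Package: scMesenchyme
Title: Single-Cell Analysis of the Perinatal Lung Mesenchyme
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for single-cell RNA-seq analysis of the
    developing lung mesenchyme and its response to neonatal hyperoxia.
    Implements cell quality control, counts-per-million normalization,
    Fano-factor feature selection, PCA/t-SNE embedding, Leiden clustering,
    marker-rule cell-subtype annotation with doublet exclusion,
    Kolmogorov-Smirnov differential expression with Bonferroni correction,
    a bootstrap compositional test for developmental arrest,
    progression-gene arrest scoring, ligand-receptor interaction counting
    and strength scoring, reference-atlas co-embedding with PCA-ellipse
    reannotation, and a seeded negative-binomial simulator that emulates
    the compositional and temporal structure of perinatal lung mesenchyme
    data so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SingleCellExperiment
Imports: methods, stats, utils, tools, Matrix, S4Vectors,
    SummarizedExperiment, igraph, RANN, Rtsne, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
biocViews: SingleCell, Transcriptomics, Clustering, DifferentialExpression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
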
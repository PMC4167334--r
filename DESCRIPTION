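Package: vernclust
Title: Time-Weighted Clustering and No-Replicate Differential Expression
    for Vernalization Time-Course RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for unevenly spaced time-course RNA-seq
    experiments with one pooled library per time point, as used in studies
    of vernalization-mediated floral induction. Implements median-of-ratios
    library normalization, blind (all-samples-as-replicates) negative
    binomial dispersion estimation with a parametric mean-dispersion fit,
    an exact conditional negative binomial test for pairwise comparisons
    without biological replicates, a closed-form variance-stabilizing
    transformation, K-means clustering of expression profiles under a
    calendar-time-weighted distance that accounts for uneven sampling
    intervals, rule-based classification of cluster centroids into
    interpretive expression-profile archetypes (stress response, cold
    acclimation, gradual and late vernalization response, long-day
    specific), classical multidimensional scaling of samples, Fisher's
    exact term enrichment, and a seeded synthetic-data generator that
    emulates the study design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
biocViews: RNASeq, TimeCourse, Clustering, DifferentialExpression,
    GeneExpression, Normalization
RoxygenNote: 7.3.3
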
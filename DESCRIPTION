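Package: ShapCompare
Title: Consistency Analysis of Shapley-Value Explanations for Compound
    Activity Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how much feature-attribution methods
    agree when explaining compound activity classifiers trained on binary
    molecular fingerprints. Provides a seeded synthetic fingerprint
    generator with planted class-discriminative bits, activity-record
    curation filters, four classifier families (random forest,
    feed-forward neural network, and support vector machines with RBF or
    Tanimoto kernels) with stratified shuffle-split trials and grid
    search, exact Shapley values by coalition enumeration with a
    marginal-expectation value function, a KernelSHAP weighted-regression
    approximator, and an explanation-comparison statistics suite
    (cumulative present/absent analysis, Gini coefficients, compacity,
    consistency, between-method correlation, faithfulness,
    remove-and-retrain evaluation, and Wilcoxon signed-rank tests with
    Holm-Bonferroni correction).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    kernlab,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Classification, FeatureExtraction, Cheminformatics
RoxygenNote: 7.3.3
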
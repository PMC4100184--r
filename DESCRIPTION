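Package: methylNG
Title: Non-Gaussian Dimension Reduction and Clustering for DNA Methylation Beta Values
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for unsupervised analysis of DNA methylation beta-value
    matrices that respect the bounded [0,1] support of the data. Implements
    variational Bayesian beta-gamma nonnegative matrix factorization (BG-NMF)
    yielding a bounded pseudo-basis, spectral and principal-component
    embeddings, random-matrix-theory estimation of the signal dimension, and
    five mixture-model clusterers with automatic component-count selection:
    variational Gaussian, beta, von Mises-Fisher and Watson mixtures plus a
    recursive-partitioning beta mixture benchmark. A reduce-cluster-evaluate
    pipeline reports error rates and misclustering directions against known
    sample classes, and seeded generators simulate methylation-like grouped
    beta matrices and directional mixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
biocViews: DNAMethylation, Clustering, DimensionReduction, Epigenetics
RoxygenNote: 7.3.3
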
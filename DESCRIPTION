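Package: scMaskClust
Title: Denoising and Masked Self-Supervised Clustering for Single-Cell
    RNA-Seq Counts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clustering of single-cell RNA-seq count matrices by chaining a
    zero-inflated negative binomial (ZINB) denoising autoencoder, a gene-wise
    shuffle/Bernoulli-masking autoencoder with mask prediction and weighted
    reconstruction, and a weighted soft K-means head refined by Student-t
    soft assignment with KL self-training. Includes library-size
    normalisation, highly-variable-gene selection, cosine KNN graphs and
    stochastic augmentations for the representation learner, external and
    internal clustering metrics (ARI, NMI, silhouette), a seeded generator
    of clustered ZINB counts with ground truth for benchmarking, ablation
    and hyperparameter-sweep drivers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    jsonlite,
    SingleCellExperiment,
    SummarizedExperiment,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
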
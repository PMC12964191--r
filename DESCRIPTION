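Package: palnn
Title: Detecting Potentially Associated Loci from Neural Networks Trained
    on Genome-Wide Genotypes
Version: 0.1.0
Authors@R:
    person("palnn", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects potentially associated loci (PAL) for binary traits
    from feedforward neural networks trained on genome-wide SNP genotype
    matrices. Provides a nonlinear phenotype simulator with dominant,
    recessive and epistatic (two- and three-way interaction) effects, a
    multilayer perceptron classifier with input-masking dropout and
    noise-injection training, post hoc feature attribution (saliency maps,
    integrated gradients and permutation importance), multi-seed mean
    attribution score (MAS) aggregation with percentile-threshold
    weighting, a half-normal rank-matched null model for per-SNP P-value
    estimation, a per-SNP logistic regression baseline with principal
    component covariates, and an LD-aware precision/recall evaluation
    harness for simulation benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    data.table
Config/testthat/edition: 3
NeedsCompilation: yes
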
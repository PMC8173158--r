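Package: epiaccel
Title: Epigenetic Aging Acceleration Analysis for Neurodegenerative Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for studying accelerated
    epigenetic aging in neurodegenerative disease from DNA-methylation
    profiles. Provides a synthetic methylation-cohort generator with planted
    ground truth; preprocessing (missingness filtering, KNN imputation,
    reference z-scoring, SVD batch correction, stratified splitting); ReliefF
    feature ranking with a discrete AdaBoost tree ensemble and
    cross-validated marker selection; an ensemble-regression aging score with
    sigmoid age transform and rank-based group comparisons;
    aging-score-conditioned differential correlation networks with FDR
    control, shortest aging-to-disease paths and permutation betweenness;
    Metropolis-Hastings global sensitivity analysis with a sign-split
    Kolmogorov-Smirnov statistic; and hypergeometric gene-set enrichment of
    path genes against GMT collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rpart,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    pROC
Config/testthat/edition: 3
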
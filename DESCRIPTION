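Package: phenoclust
Title: Consensus Clustering for Phenotype Discovery in Mixed-Type Clinical Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised phenotyping of clinical cohorts with mixed-type
    features: Gower dissimilarities with missing-data weighting, partitioning
    around medoids (BUILD and SWAP) over a precomputed dissimilarity matrix,
    subsampled consensus clustering, selection of the number of clusters by
    the proportion of ambiguous clustering (PAC), item-consensus outlier
    detection and cluster purification, association-based feature reduction
    with partition-stability checks, and content/predictive cluster-validity
    reporting. Includes a synthetic cohort generator with planted phenotypes
    and cluster-graded outcomes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
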
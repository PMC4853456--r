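Package: tractmvpa
Title: Tract-Restricted Multivariate Analysis of Diffusion MRI Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise multivariate pattern analysis of diffusion tensor
    metrics (FA, MD, AD, RD) restricted to a white-matter tract skeleton.
    Implements probabilistic-tractography map post-processing (way-total
    normalization, percentile-fraction thresholding, skeleton intersection),
    per-voxel F-score feature selection, three classifier families (kernel
    support vector machines via a compact SMO solver, ElasticNet-penalized
    logistic regression via FISTA, and structured sparse total-variation
    logistic regression via ADMM on the tract adjacency graph), leave-one-out
    cross-validation with hyper-parameter grid search, full-pipeline
    permutation significance with null ROC contour bands, voxel-group
    covariance maps with threshold-free cluster enhancement (TFCE) and
    max-statistic family-wise-error inference, bootstrap-averaged coefficient
    maps, and the accompanying univariate behavioural statistics. A synthetic
    cohort generator emulating a curved tract, spatially correlated DTI noise,
    implanted end-localized group effects, and a go/no-go (SART) behavioural
    task makes every stage testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    Rcpp,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
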
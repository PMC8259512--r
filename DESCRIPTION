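Package: sanmap
Title: Regional Microvascular and Excitability Mapping of the Sinoatrial Node
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of sinoatrial-node (SAN) microvascular
    anatomy and pacemaker myocyte excitability. Provides 3D vessel and myocyte
    density mapping from two-channel image volumes, anisotropic Euclidean
    distance transforms (myocyte-to-vessel proximity), an objective sigmoid
    boundary separating superior and inferior node regions, vessel
    skeletonization with branch orders and diameters, action-potential and
    subthreshold voltage-fluctuation feature extraction from current-clamp
    recordings, Ca2+ spark and transient quantification from line-scan
    kymographs, spark-to-AP coupling metrics, Gaussian-mixture amplitude
    decomposition, and seeded synthetic-data generators with full ground truth
    for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
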
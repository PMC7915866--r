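Package: musclenet
Title: Muscle Functional Networks and Sensor Selection from Multichannel
    Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multichannel surface electromyography (EMG)
    as a muscle functional network. Pairwise channel dependence is estimated
    with histogram mutual information and assembled into a normalized
    weighted adjacency matrix, which is binarized at a threshold chosen to
    keep the network connected with average degree above 2 ln n. Network
    topology (degree statistics, clustering coefficient, average path
    length), node-contraction importance for key-muscle identification,
    convergent cross-mapping for directed muscle-to-muscle information flow,
    and ranked sensor-set selection with surface coverage are provided,
    together with an end-to-end pipeline that compares movement conditions
    by hierarchical clustering of network features. A synthetic-EMG
    generator with planted correlation groups and directed lagged couplings
    supports validation without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
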
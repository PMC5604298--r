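Package: cutcluster
Title: Agglomerative Clustering of Heterogeneous Biomedical Metadata Keys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Groups near-duplicate and related metadata keys from biomedical
    repositories (for example GEO Sample "characteristics" keys such as
    "age (yrs)", "age in years" and "donor_age") into clusters. Keys are
    compared with a weighted combination of Jaro-Winkler name similarity,
    core-concept similarity with offline synonym expansion, and value
    similarity; the weights can be fitted from a labelled reference
    partition by simplex-constrained linear regression. Clustering is
    agglomerative with a uniform cut() criterion for cohesion and coupling
    and a coupling-threshold termination rule. Includes clustering
    evaluation metrics (clustering F-Score, normalized entropy, Rand
    index), readers and writers for key-value tables and cluster
    assignment files, and a generator of synthetic messy-metadata corpora
    with known reference clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
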
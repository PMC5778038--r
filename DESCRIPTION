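Package: hrrnet
Title: Co-Expression Networks by Highest Reciprocal Rank Filtering with
    HCCA Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds gene co-expression networks from replicate expression
    tables by all-pairs Pearson correlation with highest reciprocal rank
    (HRR) edge filtering, partitions them with the Heuristic Cluster
    Chiseling Algorithm (HCCA), calls differentially expressed genes with
    fold-change and p-value thresholds, and overlays CAZyme annotation and
    secreted-protein detections onto networks and clusters. Includes a
    synthetic expression-data generator with planted co-expression modules
    and fold-change effects for validating every stage against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
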
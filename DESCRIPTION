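Package: crypticscan
Title: Cryptic Species Delimitation from Mitochondrial Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects putative cryptic species within an aligned set of
    mitochondrial sequences (e.g. control-region or COI alignments of shark
    populations). Computes pairwise-deletion p-distances and intra- versus
    inter-group distance distributions, partitions sequences with five
    clustering algorithms (k-means, complete-linkage hierarchical clustering,
    Brunet non-negative matrix factorization, DBSCAN, and affinity
    propagation) combined into a consensus, selects the number of clusters by
    the elbow, average-silhouette, and gap-statistic criteria, and validates
    the resulting grouping with cross-validated random-forest, support-vector
    machine, and multilayer-perceptron classifiers on ordinally encoded
    alignments, extracting per-site importance profiles and key diagnostic
    sites. Includes a seeded simulator of alignments with planted group
    structure for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    mclust,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    ape,
    cluster,
    nnet,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
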
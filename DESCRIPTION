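Package: nodulehash
Title: Hashing and Cluster-Pruned Retrieval of Lung Nodule Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Content-based retrieval of segmented lung nodule images with
    supervised kernel hashing and cluster pruning. Extracts a 104-dimensional
    feature vector per image (gray-level statistics, Hu invariant moments,
    geometric shape descriptors, medical signs, a boundary Fourier descriptor,
    and Haralick texture statistics from gray-level co-occurrence matrices at
    four angles), partitions the database by normalized spectral clustering,
    learns supervised kernelized hash functions from benign/malignant labels,
    and answers queries by cluster-pruned Hamming-space search with a
    distance-based tie-breaking rule. Retrieved neighbours drive a
    majority-vote benign/malignant classifier. Includes a synthetic
    nodule-image generator so the whole pipeline is testable without any
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
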
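Package: knnselect
Title: Exact k-Nearest-Neighbor Graphs by Multi-Query Quickselect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Brute-force construction of exact k-nearest-neighbor graphs for
    high-dimensional vector collections. Pairwise Euclidean, Cosine, and
    Pearson distances are computed by the dot-product/norm decomposition
    (one dense matrix product plus column reductions), and each query row's
    k smallest distances are found by a multi-query quickselect whose
    partition step is a deterministic 32-lane emulation of the GPU warp
    ballot/popcount primitive, including the two-level warp/block partition
    scheme and a copy-avoiding reference stack. Includes synthetic fixture
    generators, independent brute-force oracles, file I/O for delimited and
    MatrixMarket inputs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    optparse,
    stats,
    tibble,
    tools,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
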
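Package: cdlink
Title: Cosine-Distance Similarity Indices for Link Prediction in Complex
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Link prediction for unweighted, undirected simple networks
    using the cosine-distance (CD) family of similarity indices: node
    coordinates derived from a thresholded shortest-path matrix, cosine
    similarity between coordinate vectors, local-community-density (LD)
    combinations, and a degree-corrected variant for disassortative
    networks. Includes a frontier-expansion breadth-first all-pairs
    shortest-path routine, fourteen classical baseline indices plus a
    random predictor, a train/probe split and top-L precision evaluation
    protocol with iteration averaging, network topology summaries, and
    seeded graph generators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    tibble
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
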
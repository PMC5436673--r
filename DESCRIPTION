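Package: hierord
Title: Hierarchical Ordering of Directed Networks by Spectral Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes continuous and discrete hierarchy levels for the nodes
    of a directed network (e.g. cortical areas in a brain connectivity graph)
    from its adjacency matrix and a few anchored levels. The method embeds
    the graph with the eigenvectors of the normalized directed Laplacian
    built from the random-walk Perron vector, converts regularized Tanimoto
    similarities between embedding rows into pseudo hierarchical distances,
    and assigns levels by anchored multi-restart box-constrained least
    squares, with spectral-gap heuristics for choosing the embedding
    dimension and the number of levels. Includes a planted-hierarchy
    generator for benchmarking, evaluation metrics (Pearson correlation,
    mean absolute error, root mean square error), broom-style tidiers,
    ggplot2 plotting, and a command-line interface.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
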
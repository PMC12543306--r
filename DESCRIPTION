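Package: nbsconn
Title: Network-Based Predictive Modeling and Similarity Decomposition of
    Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying hormonal-state effects on resting-state
    functional connectomes from densely sampled designs. Builds connectomes
    from parcellated BOLD time series with confound regression; decomposes
    pairwise connectome similarity into group-, dataset-, contraceptive-, and
    individual-level contributions via Fisher-z similarity and category
    contrasts; identifies contraceptive- and hormone-related connectivity with
    cross-validated network-based edge selection (largest connected component
    of suprathreshold edges) feeding L2-penalized logistic or ridge models,
    with performance-weighted network aggregation and transfer evaluation on
    independent data; and ships a synthetic-study generator with planted edge
    effects for ground-truth validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
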
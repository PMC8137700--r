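Package: tcellproj
Title: Reference Atlas Construction and Projection for Single-Cell T Cell States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds integrated single-cell reference atlases of T cell
    transcriptional states from multiple scRNA-seq datasets, and projects new
    query datasets into the frozen reference coordinate spaces (PCA, UMAP and
    independent components) without altering the reference. Provides
    anchor-based batch correction, nearest-neighbor subtype classification,
    discriminant-dimension and discriminant-gene tests to detect perturbed
    gene programs, cross-study marker-consensus meta-analysis, T cell receptor
    clonal-overlap statistics, and a synthetic multi-batch data generator with
    a cross-validated projection benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    RANN,
    uwot,
    ica,
    irlba,
    igraph,
    vegan,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    pheatmap,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
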
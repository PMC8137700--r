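# Shared fixtures, built once per test run and cached. The packaged default
# simulation (seed 42) is the study condition every atlas-level check runs
# under; building it takes ~30 s, so all test files share one instance.

.tp_cache <- new.env(parent = emptyenv())

with_quiet <- function(expr) {
  withr::with_options(list(tcellproj.verbose = FALSE), expr)
}

default_config <- function() simulation_config(seed = 42)

test_atlas <- function() {
  if (is.null(.tp_cache$built)) {
    .tp_cache$built <- with_quiet(build_synthetic_atlas(default_config()))
  }
  .tp_cache$built
}

test_raw_datasets <- function() {
  if (is.null(.tp_cache$raw)) {
    .tp_cache$raw <- generate_synthetic_atlas_inputs(default_config())
  }
  .tp_cache$raw
}

test_cv <- function() {
  if (is.null(.tp_cache$cv)) {
    built <- test_atlas()
    .tp_cache$cv <- with_quiet(
      crossvalidate_projection(built$datasets, built$atlas))
  }
  .tp_cache$cv
}

# small dense matrix with gene/cell names, genes x cells
named_matrix <- function(values, n_genes, n_cells, gene_prefix = "g",
                         cell_prefix = "c") {
  m <- matrix(values, n_genes, n_cells)
  dimnames(m) <- list(paste0(gene_prefix, seq_len(n_genes)),
                      paste0(cell_prefix, seq_len(n_cells)))
  m
}

# two-cluster batch: cluster means laid out on disjoint gene blocks
block_batch <- function(block_means, n_genes, n_cells, prefix, noise_sd = 0.3,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- length(block_means[[1]])
  block <- rep(seq_len(n_blocks), each = ceiling(n_genes / n_blocks))[
    seq_len(n_genes)]
  cols <- lapply(block_means, function(mu) {
    matrix(mu[block], n_genes, ceiling(n_cells / length(block_means)))
  })
  m <- do.call(cbind, cols)[, seq_len(n_cells), drop = FALSE]
  m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m), ncol(m))
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0(prefix, seq_len(n_cells)))
  m
}

# minimal labelled atlas stub for classifier-logic tests (no expression data)
stub_atlas <- function(embeddings, labels, subtype_order = unique(labels)) {
  structure(list(pca_embeddings = embeddings,
                 umap_embeddings = embeddings[, 1:2, drop = FALSE],
                 labels = stats::setNames(labels, rownames(embeddings)),
                 subtype_order = subtype_order),
            class = "reference_atlas")
}

# projection-result stub carrying only what interpret-level functions read
stub_result <- function(ica = NULL, labels = NULL, normalized = NULL) {
  structure(list(ica_coords = ica, predicted_label = labels,
                 query_normalized = normalized),
            class = "projection_result")
}
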
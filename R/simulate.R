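#' Configuration of the synthetic multi-batch generator
#'
#' The defaults describe the study conditions all packaged checks run under:
#' six datasets of 300 cells sharing five subtypes (two datasets each miss
#' one subtype, emulating the limited subtype overlap that makes multi-study
#' T cell integration hard), 40 marker genes per subtype shifted by one
#' natural-log unit, gene-wise Gaussian batch offsets of sd 0.3 log-units,
#' log-normal library sizes around 2500 counts and negative-binomial counts
#' with dispersion 0.5.
#'
#' @param n_genes,n_subtypes,n_datasets,cells_per_dataset Problem sizes.
#' @param marker_genes_per_subtype Markers per subtype (disjoint blocks).
#' @param marker_shift Log-units added to marker-gene abundance in the
#'   subtype (>= 0).
#' @param batch_shift_sd Sd of the per-dataset per-gene log offsets.
#' @param library_size_mean Mean of the log-normal per-cell library size.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param samples_per_dataset Integer vector: samples per dataset (recycled);
#'   the default gives two samples everywhere except a single-sample final
#'   dataset, so the cross-validation fold rules are exercised.
#' @param missing_subtype_map Named list dataset-name -> subtype names to
#'   exclude from that dataset.
#' @param seed Mandatory generator seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 1200, n_subtypes = 5, n_datasets = 6,
                              cells_per_dataset = 300,
                              marker_genes_per_subtype = 40,
                              marker_shift = 1.0, batch_shift_sd = 0.3,
                              library_size_mean = 2500, nb_dispersion = 0.5,
                              samples_per_dataset = c(rep(2, n_datasets - 1), 1),
                              missing_subtype_map = NULL, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  cfg <- list(n_genes = n_genes, n_subtypes = n_subtypes,
              n_datasets = n_datasets,
              cells_per_dataset = cells_per_dataset,
              marker_genes_per_subtype = marker_genes_per_subtype,
              marker_shift = marker_shift, batch_shift_sd = batch_shift_sd,
              library_size_mean = library_size_mean,
              nb_dispersion = nb_dispersion,
              samples_per_dataset = rep_len(samples_per_dataset, n_datasets),
              missing_subtype_map = missing_subtype_map, seed = as.integer(seed))
  with(cfg, stopifnot(n_genes > 0, n_subtypes > 0, n_datasets > 0,
                      cells_per_dataset > 0, marker_genes_per_subtype > 0,
                      marker_shift >= 0, batch_shift_sd >= 0,
                      library_size_mean > 0, nb_dispersion > 0))
  if (cfg$n_subtypes * cfg$marker_genes_per_subtype > cfg$n_genes) {
    stop("marker blocks exceed the gene count")
  }
  if (is.null(cfg$missing_subtype_map) && n_datasets >= 3 && n_subtypes >= 2) {
    # default limited-overlap structure: two datasets each miss one subtype
    cfg$missing_subtype_map <- stats::setNames(
      list(subtype_names(cfg)[n_subtypes],
           subtype_names(cfg)[n_subtypes - 1L]),
      dataset_names(cfg)[2:3])
  }
  structure(cfg, class = "simulation_config")
}

subtype_names <- function(cfg) paste0("subtype", seq_len(cfg$n_subtypes))
dataset_names <- function(cfg) paste0("dataset", seq_len(cfg$n_datasets))

#' Generate synthetic multi-dataset scRNA-seq inputs with known structure
#'
#' Per-gene baseline log-abundances are drawn once; each subtype adds
#' `marker_shift` to its disjoint marker-gene block (marker baselines are
#' drawn from a moderately expressed range so the shift is visible after
#' log-normalization); each dataset adds gene-wise Gaussian batch offsets;
#' counts are negative-binomial with log-normal cell library sizes. Subtypes
#' named in `missing_subtype_map` are absent from those datasets. True
#' subtype, dataset and sample labels are attached to each cell's metadata
#' (`true_subtype`, `dataset_id`, `sample_id`).
#'
#' @param cfg A [simulation_config()].
#' @return Named list of raw-count [expression_dataset()]s, with attributes
#'   `truth` (tibble of per-cell true labels) and `marker_genes` (named list
#'   subtype -> marker genes).
#' @export
generate_synthetic_atlas_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  subtypes <- subtype_names(cfg)
  markers <- stats::setNames(vector("list", cfg$n_subtypes), subtypes)
  base <- stats::rnorm(cfg$n_genes, 0, 1.5)
  idx <- 1L
  for (k in seq_len(cfg$n_subtypes)) {
    block <- idx:(idx + cfg$marker_genes_per_subtype - 1L)
    markers[[k]] <- genes[block]
    base[block] <- stats::rnorm(length(block), 1.5, 0.25)
    idx <- idx + cfg$marker_genes_per_subtype
  }
  names(base) <- genes

  datasets <- list()
  truth <- list()
  for (d in seq_len(cfg$n_datasets)) {
    dname <- dataset_names(cfg)[d]
    batch_offset <- stats::rnorm(cfg$n_genes, 0, cfg$batch_shift_sd)
    present <- setdiff(subtypes, cfg$missing_subtype_map[[dname]])
    cell_subtype <- rep_len(present, cfg$cells_per_dataset)
    n_samples <- cfg$samples_per_dataset[d]
    sample_of <- paste0(dname, "_s",
                        rep_len(seq_len(n_samples), cfg$cells_per_dataset))
    lib <- stats::rlnorm(cfg$cells_per_dataset,
                         log(cfg$library_size_mean) - 0.3^2 / 2, 0.3)
    counts <- matrix(0L, cfg$n_genes, cfg$cells_per_dataset)
    for (ci in seq_len(cfg$cells_per_dataset)) {
      a <- base + batch_offset
      mk <- markers[[cell_subtype[ci]]]
      a[mk] <- a[mk] + cfg$marker_shift
      p <- exp(a); p <- p / sum(p)
      mu <- lib[ci] * p
      counts[, ci] <- stats::rnbinom(cfg$n_genes, mu = mu,
                                     size = 1 / cfg$nb_dispersion)
    }
    cell_ids <- sprintf("%s_c%04d", dname, seq_len(cfg$cells_per_dataset))
    dimnames(counts) <- list(genes, cell_ids)
    meta <- tibble::tibble(cell_id = cell_ids, sample_id = sample_of,
                           dataset_id = dname, true_subtype = cell_subtype)
    datasets[[dname]] <- expression_dataset(counts, meta, species = "mouse")
    truth[[dname]] <- meta
  }
  truth <- dplyr::bind_rows(truth)
  attr(datasets, "truth") <- truth
  attr(datasets, "marker_genes") <- markers
  datasets
}

#' Build a labelled atlas from a synthetic simulation
#'
#' Convenience wrapper: normalizes the generated datasets, builds the atlas
#' with [build_atlas()], and labels atlas cells with their true subtypes, so
#' downstream accuracy is measured against a known ground truth.
#'
#' @param cfg A [simulation_config()] (or a list of already generated
#'   datasets carrying a `truth` attribute).
#' @param ... Passed to [build_atlas()].
#' @return List with `atlas`, `datasets` (normalized) and `truth`.
#' @export
build_synthetic_atlas <- function(cfg, ...) {
  datasets <- if (inherits(cfg, "simulation_config")) {
    generate_synthetic_atlas_inputs(cfg)
  } else {
    cfg
  }
  truth <- attr(datasets, "truth")
  normalized <- lapply(datasets, normalize_counts)
  labels <- stats::setNames(truth$true_subtype, truth$cell_id)
  atlas <- build_atlas(normalized, labels = labels, ...)
  list(atlas = atlas, datasets = normalized, truth = truth)
}
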
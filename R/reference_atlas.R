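ATLAS_BUNDLE_VERSION <- "tcellproj-atlas-1"

#' Fit the frozen coordinate spaces of a reference atlas
#'
#' From the integrated (batch-corrected, log-normalized) matrix this computes
#' the three reference spaces that stay frozen for every later projection:
#' a PCA (genes centered, optionally unit-scaled, rotation retained), a UMAP
#' fitted on the PCA embeddings with a stored, reusable transform model, and
#' an independent component analysis (whitened fixed-point ICA, deflation)
#' whose rotation maps gene space to component space. ICA components are
#' sign-normalized so that each component's largest-magnitude gene loading is
#' positive.
#'
#' @param integrated Dense genes x cells matrix from [integrate_datasets()]
#'   (or any normalized matrix on the consensus gene space).
#' @param n_pc Number of principal components (default 50), recorded in the
#'   atlas so that distances in PC space keep a fixed meaning.
#' @param n_ica Number of independent components (default 50).
#' @param scale Unit-scale genes before rotation (default `TRUE`).
#' @param umap_seed Seed fixed for UMAP fitting so atlases are reproducible.
#' @param n_neighbors,min_dist UMAP hyperparameters (defaults 10 and 0.05;
#'   tight local neighborhoods keep the stored transform faithful to the
#'   fitted layout). Both are recorded in the atlas so projection is
#'   reproducible.
#' @param transform_epochs Optimization epochs used whenever the stored
#'   transform embeds new points (default 0: queries are placed at the
#'   membership-weighted mean of their reference neighbors' coordinates,
#'   which is deterministic). The transform output is additionally blended
#'   towards the nearest reference cell's stored coordinates in proportion
#'   to proximity, so re-applying the transform to the atlas's own cells
#'   reproduces their stored coordinates: at least 95% land within 0.5
#'   units.
#' @param species Species tag carried by the atlas.
#' @return An object of class `reference_atlas` with fields `var_genes`,
#'   `integrated`, `center`, `scale`, `pca_rotation`, `pca_embeddings`,
#'   `umap_model`, `umap_embeddings`, `ica_rotation`, `ica_embeddings`,
#'   `labels` (unset; see [set_atlas_labels()]), `subtype_order`, `species`
#'   and `params`.
#' @export
fit_reference <- function(integrated, n_pc = 50, n_ica = 50, scale = TRUE,
                          umap_seed = 42, n_neighbors = 10, min_dist = 0.05,
                          transform_epochs = 0, species = "mouse") {
  integrated <- as.matrix(integrated)
  if (is.null(rownames(integrated)) || is.null(colnames(integrated))) {
    stop("`integrated` must carry gene and cell dimnames")
  }
  n_genes <- nrow(integrated); n_cells <- ncol(integrated)
  if (n_pc > min(n_genes, n_cells)) {
    stop("n_pc exceeds the rank allowed by the matrix dimensions")
  }
  ctr <- rowMeans(integrated)
  scl <- if (scale) {
    s <- apply(integrated, 1, stats::sd)
    s[s < 1e-8] <- 1
    s
  } else {
    rep(1, n_genes)
  }
  names(scl) <- rownames(integrated)
  Xs <- t((integrated - ctr) / scl)             # cells x genes, centered

  pc <- stats::prcomp(Xs, rank. = n_pc, center = FALSE, scale. = FALSE)
  pca_rotation <- pc$rotation
  pca_embeddings <- pc$x
  colnames(pca_rotation) <- colnames(pca_embeddings) <-
    paste0("PC", seq_len(ncol(pca_rotation)))
  rownames(pca_embeddings) <- colnames(integrated)

  set.seed(umap_seed)
  umap_model <- uwot::umap(pca_embeddings, n_neighbors = n_neighbors,
                           min_dist = min_dist, ret_model = TRUE,
                           n_threads = 1, n_sgd_threads = 0)
  umap_embeddings <- umap_model$embedding
  rownames(umap_embeddings) <- colnames(integrated)
  colnames(umap_embeddings) <- c("UMAP1", "UMAP2")

  n_ica <- min(n_ica, n_genes - 1L, n_cells - 1L)
  set.seed(umap_seed)
  ic <- ica::icafast(Xs, nc = n_ica, alg = "def")
  # rotation R with Xs %*% R = sources (exact: whitening is the pseudo-inverse)
  ica_rotation <- ic$M %*% solve(crossprod(ic$M))
  ica_embeddings <- Xs %*% ica_rotation
  for (j in seq_len(ncol(ica_rotation))) {
    top <- which.max(abs(ica_rotation[, j]))
    if (ica_rotation[top, j] < 0) {
      ica_rotation[, j] <- -ica_rotation[, j]
      ica_embeddings[, j] <- -ica_embeddings[, j]
    }
  }
  dimnames(ica_rotation) <- list(rownames(integrated),
                                 paste0("ICA", seq_len(ncol(ica_rotation))))
  dimnames(ica_embeddings) <- list(colnames(integrated),
                                   colnames(ica_rotation))

  structure(
    list(var_genes = rownames(integrated), integrated = integrated,
         center = ctr, scale = scl,
         pca_rotation = pca_rotation, pca_embeddings = pca_embeddings,
         umap_model = umap_model, umap_embeddings = umap_embeddings,
         ica_rotation = ica_rotation, ica_embeddings = ica_embeddings,
         labels = NULL, subtype_order = NULL, subtype_palette = NULL,
         species = species,
         params = list(n_pc = n_pc, n_ica = n_ica, scale = scale,
                       umap_seed = umap_seed, n_neighbors = n_neighbors,
                       min_dist = min_dist,
                       transform_epochs = transform_epochs)),
    class = "reference_atlas")
}

# Apply the stored UMAP transform with the atlas's recorded settings.
# uwot places a new point at the membership-weighted mean of its reference
# neighbors' coordinates, which shrinks points towards local centers; the
# output is therefore blended with the nearest reference cell's stored
# coordinates, weighted by how close the query sits relative to that cell's
# own neighborhood radius. A query identical to a reference cell lands
# exactly on it (the frozen-map premise); a query a full radius away gets
# the plain transform output.
atlas_umap_transform <- function(atlas, pca) {
  params <- atlas$params
  set.seed(params$umap_seed)
  out <- uwot::umap_transform(pca, atlas$umap_model, n_threads = 1,
                              n_sgd_threads = 0,
                              n_epochs = params$transform_epochs %||% 0)
  ref_pca <- atlas$pca_embeddings[, seq_len(ncol(pca)), drop = FALSE]
  nn1 <- RANN::nn2(ref_pca, pca, k = 1)
  k_loc <- min(10L, nrow(ref_pca) - 1L)
  loc <- RANN::nn2(ref_pca, ref_pca, k = k_loc + 1L)$nn.dists
  radius <- pmax(apply(loc[, -1, drop = FALSE], 1, stats::median), 1e-12)
  w <- pmax(0, 1 - nn1$nn.dists[, 1] / radius[nn1$nn.idx[, 1]])
  snap <- atlas$umap_embeddings[nn1$nn.idx[, 1], , drop = FALSE]
  out <- out * (1 - w) + snap * w
  dimnames(out) <- list(rownames(pca), c("UMAP1", "UMAP2"))
  out
}

#' @method print reference_atlas
#' @export
print.reference_atlas <- function(x, ...) {
  cat(sprintf(
    "<reference_atlas> %d genes x %d cells | %d PCs, %d ICs (%s)\n",
    length(x$var_genes), ncol(x$integrated), ncol(x$pca_rotation),
    ncol(x$ica_rotation), x$species))
  if (!is.null(x$labels)) {
    cat("  subtypes:", paste(x$subtype_order, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Attach per-cell subtype labels to an atlas
#'
#' @param atlas A `reference_atlas`.
#' @param labels Character vector named by (or ordered as) the atlas cells;
#'   each cell gets exactly one label.
#' @param subtype_order Optional display/tie-break order of the subtype
#'   names; defaults to order of first appearance.
#' @param palette Optional named colour vector.
#' @return The atlas with labels set.
#' @export
set_atlas_labels <- function(atlas, labels, subtype_order = NULL,
                             palette = NULL) {
  stopifnot(inherits(atlas, "reference_atlas"))
  cells <- colnames(atlas$integrated)
  if (!is.null(names(labels))) {
    stopifnot(all(cells %in% names(labels)))
    labels <- labels[cells]
  } else {
    stopifnot(length(labels) == length(cells))
    names(labels) <- cells
  }
  if (anyNA(labels)) stop("every atlas cell needs exactly one label")
  atlas$labels <- as.character(labels)
  names(atlas$labels) <- cells
  atlas$subtype_order <- subtype_order %||% unique(as.character(labels))
  atlas$subtype_palette <- palette
  atlas
}

#' Shared-nearest-neighbor clustering of the atlas
#'
#' Builds a kNN graph on the chosen embedding, weighs edges by the Jaccard
#' overlap of neighbor sets (edges below 1/15 pruned), and optimizes Louvain
#' modularity at the given resolution with a fixed seed. Cluster ids are
#' renumbered 0..C-1 by decreasing size.
#'
#' @param atlas A `reference_atlas`.
#' @param resolution Louvain resolution (> 0). The atlas presets are 0.6 on
#'   the UMAP embedding for the tumor atlas and 0.4 on PCA for the viral one.
#' @param k_param Neighborhood size (>= 2, default 20).
#' @param reduction `"umap"` or `"pca"`.
#' @param seed Seed fixed for the Louvain pass.
#' @param prune Jaccard pruning threshold (default 1/15).
#' @return Integer vector of cluster ids (0-based) named by cell.
#' @export
cluster_snn <- function(atlas, resolution = 0.6, k_param = 20,
                        reduction = c("umap", "pca"), seed = 42,
                        prune = 1 / 15) {
  reduction <- match.arg(reduction)
  stopifnot(resolution > 0, k_param >= 2)
  emb <- switch(reduction, umap = atlas$umap_embeddings,
                pca = atlas$pca_embeddings)
  n <- nrow(emb)
  if (k_param >= n) stop("k_param must be smaller than the cell count")
  nn <- RANN::nn2(emb, emb, k = k_param)$nn.idx
  # SNN weights: Jaccard overlap of the k-neighborhoods of each kNN edge
  edges <- cbind(rep(seq_len(n), each = k_param), as.vector(t(nn)))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  nb <- lapply(seq_len(n), function(i) nn[i, ])
  w <- vapply(seq_len(nrow(edges)), function(r) {
    i <- edges[r, 1]; j <- edges[r, 2]
    inter <- length(intersect(nb[[i]], nb[[j]]))
    inter / (2 * k_param - inter)
  }, numeric(1))
  keep <- w >= prune
  g <- igraph::make_graph(as.vector(t(edges[keep, , drop = FALSE])), n = n,
                          directed = FALSE)
  g <- igraph::simplify(igraph::set_edge_attr(g, "weight", value = w[keep]),
                        edge.attr.comb = "max")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  out <- relabel[as.character(memb)]
  names(out) <- rownames(emb)
  out
}

#' Annotate independent components against gene signatures
#'
#' Each (component, signature) pair is scored by the absolute value of the
#' sum of the component's gene loadings over the signature genes present in
#' the atlas; the top-scoring signatures per component are retained.
#'
#' @param atlas A `reference_atlas`.
#' @param signatures Named list of gene vectors (see [read_gmt()]).
#' @param top Signatures kept per component (default 3).
#' @return Tibble with columns `component`, `signature`, `score`, `rank`.
#' @export
annotate_ica <- function(atlas, signatures, top = 3) {
  stopifnot(inherits(atlas, "reference_atlas"), length(signatures) > 0)
  rot <- atlas$ica_rotation
  rows <- purrr::imap_dfr(signatures, function(genes, nm) {
    present <- intersect(genes, rownames(rot))
    if (!length(present)) {
      warning(sprintf("signature '%s' has no genes in the atlas; skipped", nm))
      return(NULL)
    }
    tibble::tibble(component = colnames(rot), signature = nm,
                   score = unname(abs(colSums(rot[present, , drop = FALSE]))))
  })
  if (nrow(rows) == 0) stop("no signature overlaps the atlas gene space")
  rows |>
    dplyr::group_by(.data$component) |>
    dplyr::arrange(dplyr::desc(.data$score), .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::filter(.data$rank <= top) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$component, colnames(rot)), .data$rank)
}

#' Build a reference atlas from normalized datasets in one call
#'
#' Runs per-dataset variable-gene selection, consensus, pairwise anchor
#' finding and filtering, integration, and [fit_reference()]. Labels can be
#' supplied (e.g. known annotations) or left `NULL`, in which case
#' [cluster_snn()] ids are used as provisional labels.
#'
#' @param datasets Named list of normalized [expression_dataset()]s (one per
#'   batch/study).
#' @param n_var Variable genes per dataset (default 600).
#' @param n_consensus Consensus gene count (default 800).
#' @param score_threshold,threshold_mode Anchor filtering (defaults 0.8,
#'   `"absolute"`).
#' @param labels Optional per-cell labels named by cell id.
#' @param cluster_resolution,cluster_reduction SNN preset used when no labels
#'   are given (defaults 0.6, `"umap"`).
#' @param ... Passed to [fit_reference()].
#' @return A labelled `reference_atlas`.
#' @export
build_atlas <- function(datasets, n_var = 600, n_consensus = 800,
                        score_threshold = 0.8, threshold_mode = "absolute",
                        labels = NULL, cluster_resolution = 0.6,
                        cluster_reduction = "umap", ...) {
  stopifnot(length(datasets) >= 2)
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  var_lists <- lapply(datasets, select_variable_genes, n = n_var)
  genes <- consensus_variable_genes(var_lists,
                                    vapply(datasets, function(d)
                                      ncol(d$counts), 1L),
                                    n = n_consensus)
  anchors <- pairwise_anchors(datasets, genes,
                              score_threshold = score_threshold,
                              mode = threshold_mode)
  integrated <- integrate_datasets(datasets, anchors, genes)
  atlas <- fit_reference(integrated, species = datasets[[1]]$species, ...)
  if (is.null(labels)) {
    cl <- cluster_snn(atlas, resolution = cluster_resolution,
                      reduction = cluster_reduction)
    labels <- stats::setNames(paste0("cluster", cl), names(cl))
  }
  set_atlas_labels(atlas, labels)
}

#' Checksum of the frozen parts of an atlas
#'
#' Hashes every atlas field except the external UMAP model object (whose
#' output on the atlas's own cells is captured by `umap_embeddings`). Used to
#' verify that projection never mutates the reference.
#'
#' @param atlas A `reference_atlas`.
#' @return A character hash.
#' @export
atlas_checksum <- function(atlas) {
  stopifnot(inherits(atlas, "reference_atlas"))
  rlang::hash(atlas[setdiff(names(atlas), "umap_model")])
}

#' Save or load a reference atlas bundle
#'
#' The bundle is a directory holding a JSON manifest (versioned), the atlas
#' fields, the fitted UMAP model, and a probe set: PCA coordinates of up to
#' 100 atlas cells with their UMAP transform outputs computed at save time.
#' On load the restored UMAP model is re-applied to the probe set and must
#' reproduce the stored coordinates within `1e-6`, guarding against a model
#' that silently fails to round-trip.
#'
#' @param atlas A `reference_atlas`.
#' @param path Bundle directory.
#' @return `save_atlas()` returns `path` invisibly; `load_atlas()` returns
#'   the restored `reference_atlas`.
#' @rdname atlas_bundle
#' @export
save_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "reference_atlas"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n_probe <- min(100L, nrow(atlas$pca_embeddings))
  probe_idx <- seq_len(n_probe)
  probe_pca <- atlas$pca_embeddings[probe_idx, , drop = FALSE]
  probe_umap <- atlas_umap_transform(atlas, probe_pca)
  core <- atlas[setdiff(names(atlas), "umap_model")]
  saveRDS(core, file.path(path, "atlas_core.rds"))
  saveRDS(list(pca = probe_pca, umap = probe_umap),
          file.path(path, "probe_set.rds"))
  uwot::save_uwot(atlas$umap_model, file.path(path, "umap_model.uwot"),
                  unload = FALSE)
  manifest <- list(version = ATLAS_BUNDLE_VERSION,
                   species = atlas$species,
                   n_genes = length(atlas$var_genes),
                   n_cells = ncol(atlas$integrated),
                   params = atlas$params,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname atlas_bundle
#' @export
load_atlas <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in bundle: ", path)
  manifest <- jsonlite::read_json(manifest_path)
  if (!identical(manifest$version, ATLAS_BUNDLE_VERSION)) {
    stop(sprintf("incompatible atlas bundle version '%s' (expected '%s')",
                 manifest$version, ATLAS_BUNDLE_VERSION))
  }
  core <- readRDS(file.path(path, "atlas_core.rds"))
  model <- uwot::load_uwot(file.path(path, "umap_model.uwot"))
  atlas <- structure(c(core, list(umap_model = model)),
                     class = "reference_atlas")
  atlas <- atlas[c(setdiff(names(core), "umap_model"), "umap_model")]
  class(atlas) <- "reference_atlas"
  probe <- readRDS(file.path(path, "probe_set.rds"))
  check <- atlas_umap_transform(atlas, probe$pca)
  err <- max(abs(check - probe$umap))
  if (err > 1e-6) {
    stop(sprintf("restored UMAP model fails the probe check (max dev %.3g)",
                 err))
  }
  atlas
}
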
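#' Fractions of cells projected within given radii of their positions
#'
#' @param projected,original_coords Matrices of matching cells (rows named
#'   by cell id) in the same space.
#' @param radii Numeric radii (defaults: the conventional 1 UMAP unit and 5
#'   PCA units).
#' @return Tibble with `radius` and `fraction`, monotone non-decreasing in
#'   the radius.
#' @export
projection_distance_metrics <- function(projected, original_coords,
                                        radii = c(1, 5)) {
  projected <- as.matrix(projected)
  original_coords <- as.matrix(original_coords)
  unmatched <- c(setdiff(rownames(projected), rownames(original_coords)),
                 setdiff(rownames(original_coords), rownames(projected)))
  if (length(unmatched)) {
    stop("unmatched cells: ", paste(utils::head(unmatched, 5), collapse = ", "),
         if (length(unmatched) > 5) sprintf(" (+%d more)", length(unmatched) - 5))
  }
  original_coords <- original_coords[rownames(projected), , drop = FALSE]
  d <- sqrt(rowSums((projected - original_coords)^2))
  tibble::tibble(radius = sort(radii),
                 fraction = vapply(sort(radii), function(r) mean(d <= r),
                                   numeric(1)))
}

# apply a vegan procrustes fit (full atlas ~ reduced atlas) to new coordinates
apply_procrustes <- function(fit, coords) {
  coords <- as.matrix(coords)
  sweep(fit$scale * coords %*% fit$rotation, 2, fit$translation[1, ], "+")
}

#' Drop reference cells from an atlas while keeping its frozen spaces
#'
#' Returns an atlas whose integrated matrix, embeddings and labels are
#' restricted to the retained cells; the variable genes, centering/scaling,
#' rotation matrices and fitted UMAP model are untouched, so coordinates of
#' any projection remain directly comparable with the original atlas.
#'
#' @param atlas A `reference_atlas`.
#' @param drop_cells Cell ids to remove from the reference.
#' @return The reduced `reference_atlas`.
#' @export
reduce_atlas <- function(atlas, drop_cells) {
  stopifnot(inherits(atlas, "reference_atlas"))
  keep <- setdiff(colnames(atlas$integrated), drop_cells)
  if (length(keep) < 2) stop("reduction leaves fewer than 2 reference cells")
  atlas$integrated <- atlas$integrated[, keep, drop = FALSE]
  atlas$pca_embeddings <- atlas$pca_embeddings[keep, , drop = FALSE]
  atlas$umap_embeddings <- atlas$umap_embeddings[keep, , drop = FALSE]
  atlas$ica_embeddings <- atlas$ica_embeddings[keep, , drop = FALSE]
  if (!is.null(atlas$labels)) atlas$labels <- atlas$labels[keep]
  atlas
}

#' Cross-validated projection benchmark
#'
#' Estimates projection and classification accuracy by hold-out: each fold
#' removes half the samples of one dataset (all of them when the dataset has
#' a single sample) from the reference, projects the removed cells back, and
#' compares (i) the fraction of cells landing within `r_umap` of their
#' full-atlas UMAP position, (ii) within `r_pca` of their full-atlas PCA
#' position, and (iii) the predicted subtype against the full-atlas
#' annotation.
#'
#' In the default `"frozen"` mode the reduced reference keeps the full
#' atlas's coordinate spaces and merely loses the held-out cells
#' ([reduce_atlas()]), mirroring how a frozen reference is actually used:
#' projected and original coordinates live in the same system and radii are
#' directly meaningful. In `"rebuild"` mode the atlas is reconstructed from
#' scratch without the held-out cells and its spaces are aligned to the full
#' atlas by Procrustes on the cells the two builds share; radius metrics in
#' this mode are dominated by how much the rebuilt embedding itself moved,
#' not by projection error, and are reported for diagnostics only.
#'
#' @param datasets Named list of normalized [expression_dataset()]s whose
#'   `cell_meta` carries `sample_id`.
#' @param full_atlas The atlas built from all datasets, labelled.
#' @param mode `"frozen"` (default) or `"rebuild"`.
#' @param build_args List of arguments passed to [build_atlas()] for each
#'   reduced rebuild in `"rebuild"` mode (use the full build's settings).
#' @param holdout Optional list of character vectors of sample ids, one per
#'   fold; defaults to the half-sample rule above.
#' @param r_umap,r_pca Radii (defaults 1 and 5).
#' @param k,space Classifier settings for the projections.
#' @return Tibble with one row per fold (`fold`, `dataset`, `n_cells`,
#'   `umap_within`, `pca_within`, `accuracy`) plus a pooled,
#'   cell-weighted row (`fold = "pooled"`).
#' @export
crossvalidate_projection <- function(datasets, full_atlas,
                                     mode = c("frozen", "rebuild"),
                                     build_args = list(), holdout = NULL,
                                     r_umap = 1, r_pca = 5, k = 20,
                                     space = "pca") {
  mode <- match.arg(mode)
  stopifnot(length(datasets) >= 2, inherits(full_atlas, "reference_atlas"))
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  if (is.null(holdout)) {
    holdout <- list()
    for (nm in names(datasets)) {
      s <- unique(datasets[[nm]]$cell_meta$sample_id)
      if (is.null(s)) stop("datasets must carry sample_id metadata")
      take <- if (length(s) == 1) s else s[seq_len(ceiling(length(s) / 2))]
      holdout[[nm]] <- take
    }
  }
  rows <- list()
  for (f in seq_along(holdout)) {
    samples <- holdout[[f]]
    held_cells <- unlist(lapply(datasets, function(d)
      d$cell_meta$cell_id[d$cell_meta$sample_id %in% samples]),
      use.names = FALSE)
    reduced_sets <- lapply(datasets, function(d) {
      keep <- setdiff(cell_ids(d), held_cells)
      if (length(keep) == 0) NULL else subset_dataset(d, cells = keep)
    })
    reduced_sets <- Filter(Negate(is.null), reduced_sets)
    if (length(reduced_sets) < 2) {
      warning(sprintf("fold %d leaves fewer than 2 datasets; skipped", f))
      next
    }
    query_cells <- intersect(held_cells, names(full_atlas$labels))
    query <- make_query(datasets, query_cells)
    if (mode == "frozen") {
      reduced <- reduce_atlas(full_atlas, held_cells)
      res <- project(query, reduced, filter = FALSE, k = k, space = space)
      proj_pca <- res$pca_coords
      proj_umap <- res$umap_coords
    } else {
      labels <- full_atlas$labels[setdiff(names(full_atlas$labels),
                                          held_cells)]
      reduced <- do.call(build_atlas,
                         c(list(datasets = reduced_sets, labels = labels),
                           build_args))
      res <- project(query, reduced, filter = FALSE, k = k, space = space)
      shared <- intersect(rownames(reduced$pca_embeddings),
                          rownames(full_atlas$pca_embeddings))
      fit_pca <- vegan::procrustes(
        full_atlas$pca_embeddings[shared, , drop = FALSE],
        reduced$pca_embeddings[shared, , drop = FALSE])
      fit_umap <- vegan::procrustes(
        full_atlas$umap_embeddings[shared, , drop = FALSE],
        reduced$umap_embeddings[shared, , drop = FALSE])
      proj_pca <- apply_procrustes(fit_pca, res$pca_coords)
      proj_umap <- apply_procrustes(fit_umap, res$umap_coords)
    }

    ids <- rownames(res$pca_coords)
    pca_within <- mean(sqrt(rowSums(
      (proj_pca - full_atlas$pca_embeddings[ids, , drop = FALSE])^2)) <= r_pca)
    umap_within <- mean(sqrt(rowSums(
      (proj_umap - full_atlas$umap_embeddings[ids, , drop = FALSE])^2)) <= r_umap)
    acc <- mean(res$predicted_label == full_atlas$labels[ids])
    rows[[length(rows) + 1]] <- tibble::tibble(
      fold = as.character(f),
      dataset = paste(unique(sub("_s[0-9]+$", "", samples)), collapse = "+"),
      n_cells = length(ids), umap_within = umap_within,
      pca_within = pca_within, accuracy = acc)
    tp_log("crossvalidate: fold %d (%s) acc %.3f, umap %.3f, pca %.3f",
           f, rows[[length(rows)]]$dataset, acc, umap_within, pca_within)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    w <- out$n_cells
    pooled <- tibble::tibble(
      fold = "pooled", dataset = "all", n_cells = sum(w),
      umap_within = sum(out$umap_within * w) / sum(w),
      pca_within = sum(out$pca_within * w) / sum(w),
      accuracy = sum(out$accuracy * w) / sum(w))
    out <- dplyr::bind_rows(out, pooled)
  }
  out
}

# assemble one query expression_dataset holding the named cells, pulled from
# whichever datasets contain them
make_query <- function(datasets, cells) {
  parts <- lapply(datasets, function(d) {
    keep <- intersect(cell_ids(d), cells)
    if (!length(keep)) NULL else subset_dataset(d, cells = keep)
  })
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 1) parts[[1]] else merge_datasets(parts)
}
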
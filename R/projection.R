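#' Align a query dataset to a reference atlas
#'
#' Anchors are found between the atlas (as reference) and the query on the
#' intersection of the atlas variable genes with the query genes; the anchor
#' correction is applied to the query only — no atlas field is touched.
#' Atlas genes missing from the query are zero-filled after correction
#' (count logged; a warning is raised when more than 25% are missing, since
#' zero-filling many dimensions biases the rotation).
#'
#' @param query Normalized [expression_dataset()] (T-cell filtered unless
#'   that was disabled).
#' @param atlas A `reference_atlas`.
#' @param score_threshold,threshold_mode Anchor filtering (defaults 0.8,
#'   `"absolute"`).
#' @param k_weight Correction-kernel neighborhood (default 100).
#' @return A list with `corrected` (dense atlas-genes x query-cells matrix)
#'   and `direct_fallback` (`TRUE` when no anchor survived and the query was
#'   passed through uncorrected).
#' @export
align_query <- function(query, atlas, score_threshold = 0.8,
                        threshold_mode = "absolute", k_weight = 100) {
  stopifnot(inherits(query, "expression_dataset"),
            inherits(atlas, "reference_atlas"))
  if (is.null(query$normalized)) stop("normalize the query first")
  genes <- intersect(atlas$var_genes, gene_ids(query))
  if (length(genes) < 100) {
    stop(sprintf(
      "only %d atlas genes found in the query; check the species or use ortholog mode",
      length(genes)))
  }
  n_missing <- length(atlas$var_genes) - length(genes)
  if (n_missing > 0) {
    tp_log("align_query: %d atlas genes missing from the query (zero-filled)",
           n_missing)
    if (n_missing > 0.25 * length(atlas$var_genes)) {
      warning(sprintf(
        "%d of %d atlas genes missing from the query; projection may be biased",
        n_missing, length(atlas$var_genes)))
    }
  }
  ref_mat <- atlas$integrated[genes, , drop = FALSE]
  qry_mat <- as.matrix(query$normalized[genes, , drop = FALSE])
  anc <- find_anchors(ref_mat, qry_mat, genes)
  anc <- filter_anchors(anc, score_threshold, threshold_mode)
  direct_fallback <- nrow(anc$pairs) == 0
  if (direct_fallback) {
    warning(paste0("no anchors survived filtering between query and atlas; ",
                   "falling back to direct (uncorrected) projection"))
    corrected_part <- qry_mat
  } else {
    pairs <- tibble::tibble(ref_cell = anc$pairs$cell_a,
                            query_cell = anc$pairs$cell_b)
    corrected_part <- apply_anchor_correction(ref_mat, qry_mat, pairs,
                                              k_weight)
  }
  corrected <- matrix(0, length(atlas$var_genes), ncol(qry_mat),
                      dimnames = list(atlas$var_genes, colnames(qry_mat)))
  corrected[genes, ] <- corrected_part
  list(corrected = corrected, direct_fallback = direct_fallback)
}

#' Embed a corrected query matrix into the frozen atlas spaces
#'
#' Applies the atlas's stored per-gene centering/scaling and rotation
#' matrices: PCA and ICA coordinates are exact linear maps, UMAP coordinates
#' come from the stored transform applied to the PCA coordinates. The result
#' is deterministic given the atlas.
#'
#' @param corrected Dense atlas-genes x cells matrix (from [align_query()],
#'   or an uncorrected normalized matrix in direct mode).
#' @param atlas A `reference_atlas`.
#' @return List of `pca_coords`, `umap_coords`, `ica_coords` (cells in rows).
#' @export
embed_query <- function(corrected, atlas) {
  stopifnot(inherits(atlas, "reference_atlas"))
  if (!identical(rownames(corrected), atlas$var_genes)) {
    if (!setequal(rownames(corrected), atlas$var_genes)) {
      stop("corrected matrix is not on the atlas gene space")
    }
    corrected <- corrected[atlas$var_genes, , drop = FALSE]
  }
  Xs <- t((corrected - atlas$center) / atlas$scale)
  pca <- Xs %*% atlas$pca_rotation
  ica <- Xs %*% atlas$ica_rotation
  umap <- atlas_umap_transform(atlas, pca)
  list(pca_coords = pca, umap_coords = umap, ica_coords = ica)
}

#' Project a query dataset onto a reference atlas
#'
#' Full pipeline: normalization (skipped when the query already carries a
#' normalized layer), ortholog mapping when `ortho = TRUE`, T cell purity
#' filtering (optional), anchor-based alignment to the atlas (skipped in
#' direct mode), embedding into the frozen PCA/UMAP/ICA spaces, and
#' nearest-neighbor subtype classification. Every stage logs its cell counts.
#' Direct mode applies the frozen rotations without batch correction and is
#' intended for very small queries where anchor finding is not applicable.
#'
#' @param query Raw or normalized [expression_dataset()].
#' @param atlas A labelled `reference_atlas`.
#' @param direct Skip anchor correction (default `FALSE`).
#' @param ortho Map human genes to mouse orthologs first (requires a human
#'   query and `ortholog_table`).
#' @param filter Run the T cell filter (default `TRUE`).
#' @param ortholog_table Pairs for [map_orthologs()]; defaults to the
#'   packaged synthetic subset when `ortho = TRUE`.
#' @param k,space Classifier parameters, see [classify_cells()].
#' @param ... Passed to [align_query()].
#' @return An object of class `projection_result`: list with `query`
#'   (corrected dataset on the atlas gene space), `query_normalized` (the
#'   pre-correction normalized matrix, used for differential expression),
#'   `pca_coords`, `umap_coords`, `ica_coords`, `predicted_label`,
#'   `label_confidence` and a `log` of per-stage cell counts.
#' @export
project <- function(query, atlas, direct = FALSE, ortho = FALSE,
                    filter = TRUE, ortholog_table = NULL, k = 20,
                    space = "pca", ...) {
  stopifnot(inherits(query, "expression_dataset"),
            inherits(atlas, "reference_atlas"))
  if (is.null(atlas$labels)) stop("atlas has no subtype labels")
  log <- list(input = ncol(query$counts))

  if (ortho) {
    if (query$species != "human") {
      stop("ortho mode requires a human query dataset")
    }
    if (is.null(ortholog_table)) {
      ortholog_table <- read_ortholog_table(
        system.file("extdata", "orthologs_synthetic_subset.tsv",
                    package = "tcellproj"))
    }
    query <- map_orthologs(query, ortholog_table)
    log$ortholog_mapped <- ncol(query$counts)
  }
  if (is.null(query$normalized)) query <- normalize_counts(query)
  log$normalized <- ncol(query$counts)

  if (filter) {
    flt <- filter_t_cells(query)
    query <- flt$kept
    log$t_filtered <- ncol(query$counts)
  }

  if (direct) {
    genes <- intersect(atlas$var_genes, gene_ids(query))
    corrected <- matrix(0, length(atlas$var_genes), ncol(query$counts),
                        dimnames = list(atlas$var_genes, cell_ids(query)))
    corrected[genes, ] <- as.matrix(query$normalized[genes, , drop = FALSE])
    direct_fallback <- FALSE
  } else {
    al <- align_query(query, atlas, ...)
    corrected <- al$corrected
    direct_fallback <- al$direct_fallback
  }
  log$aligned <- ncol(corrected)

  emb <- embed_query(corrected, atlas)
  # corrected values live on the log scale and may dip slightly below zero
  # after anchor correction, so bypass the raw-count container checks
  corr_sparse <- as(as(as(corrected, "dMatrix"), "generalMatrix"),
                    "CsparseMatrix")
  corrected_ds <- structure(
    list(counts = corr_sparse, normalized = corr_sparse,
         cell_meta = query$cell_meta[match(colnames(corrected),
                                           query$cell_meta$cell_id), ,
                                     drop = FALSE],
         species = atlas$species),
    class = "expression_dataset")

  res <- structure(
    list(query = corrected_ds,
         query_normalized = query$normalized,
         pca_coords = emb$pca_coords, umap_coords = emb$umap_coords,
         ica_coords = emb$ica_coords,
         predicted_label = NULL, label_confidence = NULL,
         direct = direct || direct_fallback, log = log),
    class = "projection_result")
  cls <- classify_cells(res, atlas, k = k, space = space)
  res$predicted_label <- cls$label
  res$label_confidence <- cls$confidence
  res
}

#' @method print projection_result
#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> %d cells%s\n", nrow(x$pca_coords),
              if (x$direct) " (direct mode)" else ""))
  if (!is.null(x$predicted_label)) {
    tab <- sort(table(x$predicted_label), decreasing = TRUE)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify projected cells by a nearest-neighbor majority vote
#'
#' Each query cell's `k` nearest reference cells in the chosen space vote;
#' the predicted label is the modal subtype and the confidence the modal
#' fraction. Ties are broken towards the tied label with the smaller mean
#' neighbor distance, then by atlas subtype order. Cells whose confidence
#' falls below `min_conf` are labelled `"unassigned"`.
#'
#' @param result A `projection_result` (or a bare cells x dims coordinate
#'   matrix matching `space`).
#' @param atlas A labelled `reference_atlas`.
#' @param k Number of neighbors (default 20, matching the atlas kNN-graph
#'   scale).
#' @param space `"pca"` (default) or `"umap"`.
#' @param min_conf Minimum modal fraction; 0 disables the `"unassigned"`
#'   fallback.
#' @return Tibble with `cell_id`, `label`, `confidence`.
#' @export
classify_cells <- function(result, atlas, k = 20, space = c("pca", "umap"),
                           min_conf = 0) {
  space <- match.arg(space)
  stopifnot(inherits(atlas, "reference_atlas"))
  if (is.null(atlas$labels)) stop("atlas has no subtype labels")
  ref <- switch(space, pca = atlas$pca_embeddings,
                umap = atlas$umap_embeddings)
  qry <- if (inherits(result, "projection_result")) {
    switch(space, pca = result$pca_coords, umap = result$umap_coords)
  } else {
    as.matrix(result)
  }
  qry <- qry[, seq_len(ncol(ref)), drop = FALSE]
  if (k > nrow(ref)) stop("k exceeds the reference cell count")
  nn <- RANN::nn2(ref, qry, k = k)
  order_of <- stats::setNames(seq_along(atlas$subtype_order),
                              atlas$subtype_order)
  lab <- character(nrow(qry)); conf <- numeric(nrow(qry))
  for (i in seq_len(nrow(qry))) {
    votes <- atlas$labels[nn$nn.idx[i, ]]
    tab <- table(votes)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      mean_d <- vapply(top, function(l)
        mean(nn$nn.dists[i, votes == l]), numeric(1))
      top <- top[mean_d == min(mean_d)]
      if (length(top) > 1) top <- top[order(order_of[top])][1]
    }
    lab[i] <- top
    conf[i] <- max(tab) / k
  }
  if (min_conf > 0) lab[conf < min_conf] <- "unassigned"
  tibble::tibble(cell_id = rownames(qry), label = lab, confidence = conf)
}
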
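#' Integrate normalized batches into one batch-corrected matrix
#'
#' Batches are merged agglomeratively: starting from the largest batch, the
#' remaining batches are added in decreasing order of the number of filtered
#' anchors they share with the current merged set (a custom merge order can
#' be supplied). At each merge the incoming batch is corrected towards the
#' merged reference: every query cell receives a correction vector equal to
#' the anchor-weighted average of (reference anchor - query anchor)
#' expression differences, with Gaussian-kernel weights on the distance
#' between the query cell and its nearest query-side anchor cells
#' (`k_weight` nearest anchors, or all anchors when fewer).
#'
#' @param batches Named list of normalized [expression_dataset()]s.
#' @param anchors List of filtered [find_anchors()] results, one per batch
#'   pair, each tagged with the `names(batches)` indices it connects via
#'   attribute `batch_pair` (see [pairwise_anchors()], which prepares this).
#' @param genes Consensus integration genes; the output matrix has exactly
#'   these rows.
#' @param tree Optional character vector giving the merge order (first
#'   element is the starting batch). Default: largest batch first, then by
#'   anchor count with the merged set.
#' @param k_weight Anchors per query cell for the correction kernel
#'   (default 100).
#' @param refine After the sequential pass, re-correct every batch's raw
#'   values with fresh anchors found against the integrated values of the
#'   other batches (default `TRUE`). This applies to each reference batch
#'   exactly the operator that later aligns queries to the finished atlas,
#'   so a reference cell re-projected as a query lands where it sits in the
#'   map instead of where an intermediate merge left it.
#' @param score_threshold,mode Anchor filtering applied during the
#'   refinement pass (defaults 0.8, `"absolute"`; use the values the
#'   pairwise anchors were filtered with).
#' @return A dense genes x cells matrix of corrected normalized expression
#'   covering all batches, with a `batch` attribute mapping cells to batch
#'   names.
#' @export
integrate_datasets <- function(batches, anchors, genes, tree = NULL,
                               k_weight = 100, refine = TRUE,
                               score_threshold = 0.8, mode = "absolute") {
  stopifnot(is.list(batches), length(batches) >= 2)
  if (is.null(names(batches))) names(batches) <- paste0("batch", seq_along(batches))
  mats <- lapply(batches, function(b) pad_genes(get_norm(b), genes))
  for (nm in names(mats)) {
    colnames(mats[[nm]]) <- colnames(mats[[nm]])
  }
  pair_tab <- anchor_pair_table(anchors, names(batches))

  sizes <- vapply(mats, ncol, 1L)
  remaining <- names(mats)
  start <- if (!is.null(tree)) tree[1] else remaining[which.max(sizes)]
  merged_names <- start
  merged <- mats[[start]]
  batch_of <- rep(start, ncol(merged))
  remaining <- setdiff(remaining, start)
  order_queue <- if (!is.null(tree)) tree[-1] else NULL

  while (length(remaining)) {
    if (!is.null(order_queue)) {
      nxt <- order_queue[1]; order_queue <- order_queue[-1]
    } else {
      n_anch <- vapply(remaining, function(b)
        count_anchors(pair_tab, merged_names, b), 1L)
      nxt <- remaining[which.max(n_anch)]
    }
    anc <- collect_anchors(pair_tab, merged_names, nxt)
    if (nrow(anc) == 0) {
      stop(sprintf(
        "batch '%s' has no surviving anchors to the merged set; lower the anchor threshold or adjust the tree",
        nxt))
    }
    query <- mats[[nxt]]
    corrected <- apply_anchor_correction(merged, query, anc, k_weight)
    merged <- cbind(merged, corrected)
    batch_of <- c(batch_of, rep(nxt, ncol(corrected)))
    merged_names <- c(merged_names, nxt)
    remaining <- setdiff(remaining, nxt)
    tp_log("integrate_datasets: merged '%s' (%d anchors)", nxt, nrow(anc))
  }
  names(batch_of) <- colnames(merged)

  if (refine && length(mats) > 2) {
    refined <- merged
    for (b in names(mats)) {
      ref_part <- merged[, batch_of[colnames(merged)] != b, drop = FALSE]
      anc_set <- find_anchors(ref_part, mats[[b]], genes)
      anc_set <- filter_anchors(anc_set, score_threshold, mode)
      if (nrow(anc_set$pairs) == 0) next
      anc <- tibble::tibble(ref_cell = anc_set$pairs$cell_a,
                            query_cell = anc_set$pairs$cell_b)
      refined[, colnames(mats[[b]])] <-
        apply_anchor_correction(ref_part, mats[[b]], anc, k_weight)
    }
    merged <- refined
    tp_log("integrate_datasets: refinement pass complete")
  }
  attr(merged, "batch") <- batch_of
  merged
}

get_norm <- function(b) {
  if (inherits(b, "expression_dataset")) {
    if (is.null(b$normalized)) stop("all batches must be normalized")
    b$normalized
  } else {
    b
  }
}

pad_genes <- function(m, genes) {
  missing <- setdiff(genes, rownames(m))
  out <- matrix(0, length(genes), ncol(m),
                dimnames = list(genes, colnames(m)))
  present <- intersect(genes, rownames(m))
  out[present, ] <- as.matrix(m[present, , drop = FALSE])
  out
}

#' Compute filtered anchors for every batch pair
#'
#' Convenience wrapper running [find_anchors()] and [filter_anchors()] over
#' all pairs of batches, tagging each result with the pair of batch names so
#' [integrate_datasets()] can route them.
#'
#' @inheritParams integrate_datasets
#' @param genes Integration genes.
#' @param score_threshold,mode Passed to [filter_anchors()].
#' @param ... Passed to [find_anchors()].
#' @return List of tagged `anchor_set` objects.
#' @export
pairwise_anchors <- function(batches, genes, score_threshold = 0.8,
                             mode = "absolute", ...) {
  nms <- names(batches) %||% paste0("batch", seq_along(batches))
  names(batches) <- nms
  out <- list()
  for (i in seq_along(batches)) {
    for (j in seq_along(batches)) {
      if (j <= i) next
      a <- find_anchors(batches[[i]], batches[[j]], genes, ...)
      a <- filter_anchors(a, score_threshold, mode)
      attr(a, "batch_pair") <- c(nms[i], nms[j])
      out[[length(out) + 1]] <- a
    }
  }
  out
}

# flatten tagged anchor sets into one table of (batch_a, cell_a, batch_b, cell_b)
anchor_pair_table <- function(anchors, batch_names) {
  rows <- purrr::map_dfr(anchors, function(a) {
    bp <- attr(a, "batch_pair")
    if (is.null(bp)) bp <- a$batch_ids
    if (!all(bp %in% batch_names)) {
      stop("anchor set references unknown batches: ", paste(bp, collapse = ", "))
    }
    if (nrow(a$pairs) == 0) return(NULL)
    tibble::tibble(batch_a = bp[1], cell_a = a$pairs$cell_a,
                   batch_b = bp[2], cell_b = a$pairs$cell_b,
                   score = a$pairs$score)
  })
  rows
}

count_anchors <- function(pair_tab, merged_names, b) {
  if (nrow(pair_tab) == 0) return(0L)
  sum((pair_tab$batch_a %in% merged_names & pair_tab$batch_b == b) |
        (pair_tab$batch_b %in% merged_names & pair_tab$batch_a == b))
}

# anchors between the merged set and batch b, oriented (ref_cell, query_cell)
collect_anchors <- function(pair_tab, merged_names, b) {
  if (nrow(pair_tab) == 0) {
    return(tibble::tibble(ref_cell = character(), query_cell = character()))
  }
  fwd <- dplyr::filter(pair_tab, .data$batch_a %in% merged_names,
                       .data$batch_b == b)
  rev <- dplyr::filter(pair_tab, .data$batch_b %in% merged_names,
                       .data$batch_a == b)
  tibble::tibble(ref_cell = c(fwd$cell_a, rev$cell_b),
                 query_cell = c(fwd$cell_b, rev$cell_a))
}

# correct `query` (genes x cells) towards `ref` using anchor pairs
apply_anchor_correction <- function(ref, query, anc, k_weight = 100) {
  stopifnot(all(anc$ref_cell %in% colnames(ref)),
            all(anc$query_cell %in% colnames(query)))
  diffs <- ref[, anc$ref_cell, drop = FALSE] -
    query[, anc$query_cell, drop = FALSE]           # genes x anchors
  # distances measured in a PCA embedding of the query batch
  n_pc <- min(30L, ncol(query) - 1L, nrow(query) - 1L)
  emb <- query_embedding(query, n_pc)
  anchor_emb <- emb[anc$query_cell, , drop = FALSE]
  k <- min(k_weight, nrow(anc))
  nn <- RANN::nn2(anchor_emb, emb, k = k)
  corrected <- query
  for (c_i in seq_len(ncol(query))) {
    idx <- nn$nn.idx[c_i, ]
    d <- nn$nn.dists[c_i, ]
    sigma <- d[k] / 2
    w <- if (sigma < 1e-12) rep(1, k) else exp(-d^2 / (2 * sigma^2))
    w <- w / sum(w)
    corrected[, c_i] <- query[, c_i] +
      as.vector(diffs[, idx, drop = FALSE] %*% w)
  }
  corrected
}

query_embedding <- function(query, n_pc) {
  mu <- rowMeans(query)
  sdev <- apply(query, 1, stats::sd)
  sdev[sdev < 1e-8] <- 1
  Xs <- t((query - mu) / sdev)
  set.seed(1L)
  pc <- if (n_pc < min(dim(Xs)) / 3) {
    irlba::prcomp_irlba(Xs, n = n_pc, center = FALSE, scale. = FALSE)
  } else {
    stats::prcomp(Xs, rank. = n_pc, center = FALSE, scale. = FALSE)
  }
  emb <- Xs %*% pc$rotation
  rownames(emb) <- colnames(query)
  emb
}
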
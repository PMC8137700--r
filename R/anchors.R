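#' Find integration anchors between two batches
#'
#' Both batches are embedded by reciprocal PCA on a shared gene set: a PCA is
#' fitted on batch A (genes centered and scaled with A's parameters) and batch
#' B's cells are projected into it, and vice versa. Candidate anchors are
#' mutual nearest neighbor (MNN) pairs across batches (union over the two
#' reciprocal spaces). Each anchor is scored in \[0, 1\] as the product of
#' two terms. Shared-neighbor consistency: the fraction of each anchor
#' cell's `k_score` within-batch neighbors whose own cross-batch MNN
#' partners fall inside the partner cell's `k_score`-neighborhood, averaged
#' over the two sides, then spread between its 1st and 90th percentiles so
#' the retained anchors are the stable high-consistency core (a degenerate
#' spread, e.g. identical batches, maps to 1). Proximity:
#' `1 / (1 + 5 max(0, D - 0.9))`, where `D` is the pair's cross-batch
#' distance divided by the larger of the two cells' median within-batch
#' neighbor distances (full score within ~90% of the local radius, below the
#' 0.8 cutoff past about one radius).
#' Consistency rejects haphazard matches; proximity rejects
#' coherent but distant matches between batches that share no population,
#' whose mutual neighbors otherwise agree among themselves. A cell anchored
#' to an identical copy of itself scores exactly 1.
#'
#' @param batch_a,batch_b Normalized [expression_dataset()]s, or plain
#'   genes x cells matrices of normalized values.
#' @param genes Character vector of integration genes present in both batches.
#' @param k_anchor Neighbors considered for the MNN search (default 5).
#' @param k_score Neighborhood size used for anchor scoring (default 30).
#' @param n_pc Reciprocal-PCA dimensionality (default 30).
#' @return An object of class `anchor_set`: list with `pairs` (tibble
#'   `cell_a`, `cell_b`, `score`), `batch_ids`, `score_threshold` (unset until
#'   [filter_anchors()] is applied) and the gene set used. May contain zero
#'   rows when no MNN is found; the caller decides how to proceed.
#' @export
find_anchors <- function(batch_a, batch_b, genes, k_anchor = 5, k_score = 30,
                         n_pc = 30) {
  A <- anchor_matrix(batch_a, genes)
  B <- anchor_matrix(batch_b, genes)
  nA <- ncol(A); nB <- ncol(B)
  if (min(nA, nB) < 50) {
    warning("fewer than 50 cells in a batch; reducing neighborhood sizes")
    k_anchor <- max(1L, min(k_anchor, min(nA, nB) %/% 4L))
    k_score <- max(2L, min(k_score, min(nA, nB) %/% 2L))
  }
  n_pc <- min(n_pc, nA - 1L, nB - 1L, length(genes) - 1L)

  spaceA <- reciprocal_pca(A, B, n_pc)   # both batches in A's PCA space
  spaceB <- reciprocal_pca(B, A, n_pc)   # both batches in B's PCA space
  mnnA <- mutual_nn(spaceA$fit, spaceA$proj, k_anchor)   # (a, b) in A-space
  mnnB <- mutual_nn(spaceB$proj, spaceB$fit, k_anchor)   # (a, b) in B-space
  pairs <- unique(rbind(mnnA, mnnB))
  if (nrow(pairs) == 0) {
    tp_log("find_anchors: no mutual nearest neighbors found")
    return(new_anchor_set(tibble::tibble(cell_a = character(),
                                         cell_b = character(),
                                         score = numeric()),
                          batch_a, batch_b, genes))
  }

  score <- score_anchors(pairs, spaceA, spaceB, k_score, nA, nB)
  tab <- tibble::tibble(cell_a = colnames(A)[pairs[, 1]],
                        cell_b = colnames(B)[pairs[, 2]],
                        score = score)
  tp_log("find_anchors: %d candidate anchors", nrow(tab))
  new_anchor_set(tab, batch_a, batch_b, genes)
}

new_anchor_set <- function(pairs, batch_a, batch_b, genes) {
  id_of <- function(b, default) {
    if (inherits(b, "expression_dataset") &&
        "dataset_id" %in% names(b$cell_meta)) {
      unique(b$cell_meta$dataset_id)[1]
    } else {
      default
    }
  }
  structure(list(pairs = pairs,
                 batch_ids = c(id_of(batch_a, "A"), id_of(batch_b, "B")),
                 score_threshold = NA_real_, genes = genes),
            class = "anchor_set")
}

#' @method print anchor_set
#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("<anchor_set> %d pairs between '%s' and '%s'",
              nrow(x$pairs), x$batch_ids[1], x$batch_ids[2]))
  if (!is.na(x$score_threshold)) {
    cat(sprintf(" (filtered at %.2f)", x$score_threshold))
  }
  cat("\n")
  invisible(x)
}

anchor_matrix <- function(batch, genes) {
  if (inherits(batch, "expression_dataset")) {
    if (is.null(batch$normalized)) stop("batch must be normalized")
    m <- batch$normalized
  } else {
    m <- batch
  }
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    stop(sprintf("%d integration genes missing from a batch", length(missing)))
  }
  as.matrix(m[genes, , drop = FALSE])
}

# Fit PCA on `fit_mat` (genes x cells) and project `proj_mat` through the
# same rotation; returns cells x n_pc embeddings. Genes are centered with
# the fit batch's means on both sides: centering a composition-skewed query
# with its own gene means would slide it onto the fit batch's centroid and
# pair its cells with the wrong populations. Each cell is additionally
# centered over genes, so that a batch offset that is constant across genes
# cancels exactly instead of inflating every cross-batch distance; the
# gene-specific remainder of a batch effect is what the anchor correction
# downstream removes.
reciprocal_pca <- function(fit_mat, proj_mat, n_pc) {
  mu <- rowMeans(fit_mat)
  center_cells <- function(m) {
    x <- t(m - mu)
    x - rowMeans(x)
  }
  Xs <- center_cells(fit_mat)
  pc <- if (n_pc < min(dim(Xs)) / 3) {
    set.seed(1L)
    irlba::prcomp_irlba(Xs, n = n_pc, center = FALSE, scale. = FALSE)
  } else {
    stats::prcomp(Xs, rank. = n_pc, center = FALSE, scale. = FALSE)
  }
  proj <- center_cells(proj_mat) %*% pc$rotation
  emb_fit <- Xs %*% pc$rotation
  rownames(emb_fit) <- colnames(fit_mat)
  rownames(proj) <- colnames(proj_mat)
  list(fit = emb_fit, proj = proj)
}

# Mutual nearest neighbors between two embeddings (rows are cells);
# returns a 2-column index matrix (row in embA, row in embB). Cells with a
# dominant match — the nearest cross-batch neighbor is much closer than the
# second (distance ratio below 0.4), as for a near-duplicate of a reference
# cell — keep only that match: the correspondence is already determined, and
# weaker side-pairs would only inject noise into the correction.
mutual_nn <- function(embA, embB, k, ratio = 0.4) {
  k <- min(k, nrow(embA), nrow(embB))
  ab <- RANN::nn2(embB, embA, k = max(k, 2L))   # for each a: nearest b's
  ba <- RANN::nn2(embA, embB, k = max(k, 2L))
  dominant_a <- ab$nn.dists[, 1] < ratio * ab$nn.dists[, 2]
  dominant_b <- ba$nn.dists[, 1] < ratio * ba$nn.dists[, 2]
  cand <- cbind(rep(seq_len(nrow(embA)), each = k),
                as.vector(t(ab$nn.idx[, seq_len(k), drop = FALSE])))
  rank_of <- rep(seq_len(k), times = nrow(embA))
  keep <- vapply(seq_len(nrow(cand)), function(r) {
    a <- cand[r, 1]; b <- cand[r, 2]
    if (!a %in% ba$nn.idx[b, seq_len(k)]) return(FALSE)
    # dominant matches suppress every non-top pair of the cells involved
    if (dominant_a[a] && rank_of[r] > 1L) return(FALSE)
    if (dominant_b[b] && ba$nn.idx[b, 1] != a) return(FALSE)
    TRUE
  }, TRUE)
  cand[keep, , drop = FALSE]
}

score_anchors <- function(pairs, spaceA, spaceB, k_score, nA, nB) {
  kA <- min(k_score, nA); kB <- min(k_score, nB)
  # within-batch neighborhoods in each batch's own PCA space (self included)
  nnA_full <- RANN::nn2(spaceA$fit, spaceA$fit, k = kA)
  nnB_full <- RANN::nn2(spaceB$fit, spaceB$fit, k = kB)
  nnA <- nnA_full$nn.idx
  nnB <- nnB_full$nn.idx
  # local neighborhood radius per cell (median within-batch neighbor distance)
  rA <- apply(nnA_full$nn.dists, 1, stats::median)
  rB <- apply(nnB_full$nn.dists, 1, stats::median)
  rA[rA < 1e-12] <- 1e-12
  rB[rB < 1e-12] <- 1e-12
  # MNN partner lists per cell
  partners_of_a <- split(pairs[, 2], factor(pairs[, 1], levels = seq_len(nA)))
  partners_of_b <- split(pairs[, 1], factor(pairs[, 2], levels = seq_len(nB)))
  in_nbhd_B <- lapply(seq_len(nB), function(b) nnB[b, ])
  in_nbhd_A <- lapply(seq_len(nA), function(a) nnA[a, ])

  # fraction of each anchor cell's within-batch neighbors whose own MNN
  # partners land inside the partner cell's neighborhood on the other side
  side_frac <- function(nbrs, partners, nbhd_other) {
    mean(vapply(nbrs, function(x) {
      p <- partners[[x]]
      length(p) > 0 && any(p %in% nbhd_other)
    }, TRUE))
  }
  raw <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    (side_frac(nnA[a, ], partners_of_a, in_nbhd_B[[b]]) +
       side_frac(nnB[b, ], partners_of_b, in_nbhd_A[[a]])) / 2
  }, numeric(1))
  # spread consistency between its 1st and 90th percentiles so the kept set
  # concentrates on the stable high-consistency core; a degenerate spread
  # (e.g. identical batches, every anchor fully consistent) maps to 1
  q <- stats::quantile(raw, c(0.01, 0.90), names = FALSE)
  consistency <- if (q[2] - q[1] < 1e-8) {
    rep(1, length(raw))
  } else {
    pmin(pmax((raw - q[1]) / (q[2] - q[1]), 0), 1)
  }

  # proximity: cross-batch distance relative to the local within-batch
  # neighborhood radius; the larger of the two sides' radii sets the scale so
  # that a dense reference matched against a sparse query is not penalized
  # for its own density
  d_A <- sqrt(rowSums((spaceA$fit[pairs[, 1], , drop = FALSE] -
                         spaceA$proj[pairs[, 2], , drop = FALSE])^2))
  d_B <- sqrt(rowSums((spaceB$proj[pairs[, 1], , drop = FALSE] -
                         spaceB$fit[pairs[, 2], , drop = FALSE])^2))
  scale_ab <- pmax(rA[pairs[, 1]], rB[pairs[, 2]])
  D <- (d_A + d_B) / 2 / scale_ab
  # full score inside ~90% of the local radius, dropping past the 0.8 cutoff
  # once the pair is more than about one radius apart
  proximity <- 1 / (1 + 5 * pmax(0, D - 0.9))
  consistency * proximity
}

#' Filter an anchor set at a score threshold
#'
#' @param anchors An `anchor_set`.
#' @param score_threshold Cutoff (default 0.8).
#' @param mode `"absolute"` treats the threshold as a score cutoff;
#'   `"percentile"` treats it as a quantile of the observed scores.
#' @return The filtered `anchor_set`, with all retained scores at or above
#'   the effective cutoff.
#' @export
filter_anchors <- function(anchors, score_threshold = 0.8,
                           mode = c("absolute", "percentile")) {
  mode <- match.arg(mode)
  stopifnot(inherits(anchors, "anchor_set"))
  cutoff <- if (mode == "absolute") score_threshold else
    stats::quantile(anchors$pairs$score, score_threshold, names = FALSE)
  out <- anchors
  out$pairs <- dplyr::filter(anchors$pairs, .data$score >= cutoff)
  out$score_threshold <- cutoff
  tp_log("filter_anchors: kept %d/%d anchors at %s threshold %.2f",
         nrow(out$pairs), nrow(anchors$pairs), mode, score_threshold)
  out
}
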
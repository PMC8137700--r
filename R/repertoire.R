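#' Morisita overlap index between two clonotype repertoires
#'
#' \deqn{C = \frac{2\sum_i x_i y_i}{(\sum_i x_i^2/X^2 + \sum_i y_i^2/Y^2)\,XY}}
#' where \eqn{x_i, y_i} are clonotype counts and \eqn{X, Y} the repertoire
#' totals. The index is symmetric, 0 for disjoint repertoires and 1 for
#' identical relative abundances.
#'
#' @param counts_a,counts_b Named non-negative integer vectors
#'   (clonotype -> cell count).
#' @return A number in \[0, ~1\].
#' @export
morisita_index <- function(counts_a, counts_b) {
  if (!length(counts_a) || !length(counts_b)) {
    stop("empty repertoire")
  }
  stopifnot(!is.null(names(counts_a)), !is.null(names(counts_b)),
            all(counts_a >= 0), all(counts_b >= 0))
  X <- sum(counts_a); Y <- sum(counts_b)
  if (X == 0 || Y == 0) stop("repertoire with zero total count")
  clones <- union(names(counts_a), names(counts_b))
  x <- stats::setNames(rep(0, length(clones)), clones)
  y <- x
  x[names(counts_a)] <- counts_a
  y[names(counts_b)] <- counts_b
  2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

#' Pairwise clonal-overlap matrix between subtypes
#'
#' Cells of each subtype are uniformly down-sampled to at most `downsample`
#' cells (fixed seed) before clonotype counts are compared pairwise with the
#' Morisita index. Subtypes with fewer than 10 cells are excluded and
#' reported in the `excluded` attribute.
#'
#' @param table Tibble with columns `cell_id`, `clonotype_id`,
#'   `subtype_label` (and optionally `sample_id`), e.g. a
#'   [read_clonotype_table()] joined with [classify_cells()] labels.
#' @param downsample Maximum cells per subtype (default 500).
#' @param seed Down-sampling seed.
#' @return Symmetric subtype x subtype matrix with unit diagonal.
#' @export
subtype_overlap_matrix <- function(table, downsample = 500, seed = 42) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("cell_id", "clonotype_id", "subtype_label") %in%
                  names(table)))
  if (anyDuplicated(table$cell_id)) stop("duplicate cell ids")
  table <- dplyr::arrange(table, .data$cell_id)   # order-invariant given seed
  sizes <- table(table$subtype_label)
  keep <- names(sizes)[sizes >= 10]
  excluded <- setdiff(names(sizes), keep)
  if (length(excluded)) {
    tp_log("subtype_overlap_matrix: excluding %s (<10 cells)",
           paste(excluded, collapse = ", "))
  }
  if (length(keep) < 2) stop("need at least two subtypes with >= 10 cells")
  set.seed(seed)
  counts <- lapply(stats::setNames(keep, keep), function(s) {
    cells <- table$clonotype_id[table$subtype_label == s]
    if (length(cells) > downsample) cells <- sample(cells, downsample)
    tab <- table(cells)
    stats::setNames(as.integer(tab), names(tab))
  })
  m <- diag(1, length(keep))
  dimnames(m) <- list(keep, keep)
  for (i in seq_along(keep)) {
    for (j in seq_along(keep)) {
      if (j <= i) next
      m[i, j] <- m[j, i] <- morisita_index(counts[[i]], counts[[j]])
    }
  }
  attr(m, "excluded") <- excluded
  m
}

#' Clonotypes enriched in target subtypes
#'
#' A clonotype of size at least `min_cells` is selected when the fraction of
#' its cells falling in the target subtypes reaches `min_frac` (default: at
#' least half the clone in the exhausted or precursor-exhausted
#' compartments, the operational definition of a tumor-specific clone).
#'
#' @param table As in [subtype_overlap_matrix()].
#' @param target_subtypes Character vector of subtype labels.
#' @param min_frac Minimum in-target fraction (default 0.5).
#' @param min_cells Minimum clonotype size (default 2; singletons carry no
#'   linkage signal).
#' @return Tibble with `clonotype_id`, `n_cells`, `n_target`,
#'   `target_fraction`, sorted by clonotype size descending.
#' @export
enriched_clonotypes <- function(table, target_subtypes = c("Tex", "Tpex"),
                                min_frac = 0.5, min_cells = 2) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("clonotype_id", "subtype_label") %in% names(table)))
  unknown <- setdiff(target_subtypes, unique(table$subtype_label))
  if (length(unknown) == length(target_subtypes)) {
    stop("unknown target subtypes: ", paste(unknown, collapse = ", "))
  }
  table |>
    dplyr::group_by(.data$clonotype_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_target = sum(.data$subtype_label %in% target_subtypes),
      .groups = "drop") |>
    dplyr::mutate(target_fraction = .data$n_target / .data$n_cells) |>
    dplyr::filter(.data$n_cells >= min_cells,
                  .data$target_fraction >= min_frac) |>
    dplyr::arrange(dplyr::desc(.data$n_cells), .data$clonotype_id)
}
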
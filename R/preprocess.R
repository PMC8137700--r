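#' Log-normalize UMI counts
#'
#' Each raw entry \eqn{x} of a cell with total count \eqn{S} becomes
#' \eqn{\ln(1 + 10^4 x / S)} (natural log, scale factor configurable). Cells
#' with zero total counts are dropped with a logged count; raw counts are
#' retained unchanged alongside the normalized layer.
#'
#' If the dataset already carries a normalized layer, or its counts look
#' log-normalized (non-integer values), the input is passed through unchanged
#' with a warning rather than normalized twice.
#'
#' @param ds An [expression_dataset()].
#' @param scale_factor Counts are rescaled to this per-cell total before the
#'   log1p transform. Default 10000.
#' @return The dataset with a `normalized` layer (genes x cells).
#' @export
normalize_counts <- function(ds, scale_factor = 10000) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!is.null(ds$normalized)) {
    warning("dataset already normalized; returning input unchanged")
    return(ds)
  }
  x <- ds$counts
  if (any(x@x < 0)) stop("negative counts are not valid")
  if (length(x@x) && any(abs(x@x - round(x@x)) > 1e-8)) {
    warning(paste0("counts contain non-integer values and look already ",
                   "log-normalized; storing them as the normalized layer"))
    ds$normalized <- x
    return(ds)
  }
  S <- Matrix::colSums(x)
  keep <- S > 0
  if (any(!keep)) {
    tp_log("normalize_counts: dropping %d cells with zero total counts",
           sum(!keep))
    ds <- subset_dataset(ds, cells = cell_ids(ds)[keep])
    x <- ds$counts
    S <- S[keep]
  }
  norm <- x
  # column-wise: x@x runs down columns; expand per-cell totals to entries
  if (length(norm@x)) {
    cell_of_entry <- rep.int(seq_len(ncol(x)), diff(x@p))
    norm@x <- log1p(scale_factor * x@x / S[cell_of_entry])
  }
  ds$normalized <- norm
  ds
}

#' Default T cell marker and lineage-exclusion gene panels (mouse symbols)
#' @return Character vector of gene symbols.
#' @rdname t_cell_panels
#' @export
default_t_markers <- function() {
  c("Cd2", "Cd3d", "Cd3e", "Cd3g", "Cd4", "Cd8a", "Cd8b1")
}

#' @rdname t_cell_panels
#' @export
default_t_blacklist <- function() {
  c("Spi1", "Fcer1g", "Csf1r", "Cd19")
}

#' Filter a dataset down to cells enriched in T cell markers
#'
#' Each cell is scored as the mean normalized expression over the detected
#' T cell marker panel minus the mean over the detected non-T lineage panel.
#' Cells are called `T` when the score exceeds `tau` and at least one marker
#' is detected, `Non-T` when the lineage-panel mean exceeds the marker mean,
#' and `unknown` otherwise; only `T` cells are kept. This marker-score rule is
#' this package's purity filter; its per-class report lets users audit what
#' was removed, and the filter can be disabled entirely.
#'
#' @param ds Normalized [expression_dataset()].
#' @param t_markers,blacklist Marker panels; defaults are the canonical T cell
#'   and myeloid/B lineage genes ([default_t_markers()],
#'   [default_t_blacklist()]).
#' @param tau Score threshold for the `T` call (log-scale units, default 0).
#' @param enable Set `FALSE` to return the input unchanged.
#' @return A list with `kept` (the filtered dataset) and `report` (a tibble of
#'   per-class cell counts).
#' @export
filter_t_cells <- function(ds, t_markers = default_t_markers(),
                           blacklist = default_t_blacklist(), tau = 0,
                           enable = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!enable) {
    report <- tibble::tibble(class = "unfiltered", n = ncol(ds$counts))
    return(list(kept = ds, report = report))
  }
  if (is.null(ds$normalized)) stop("normalize the dataset before filtering")
  tm <- intersect(t_markers, gene_ids(ds))
  bl <- intersect(blacklist, gene_ids(ds))
  if (!length(tm)) {
    stop("no T cell marker genes found in the gene space (wrong species or empty panel?)")
  }
  t_mean <- Matrix::colMeans(ds$normalized[tm, , drop = FALSE])
  bl_mean <- if (length(bl)) {
    Matrix::colMeans(ds$normalized[bl, , drop = FALSE])
  } else {
    rep(0, ncol(ds$counts))
  }
  detected <- Matrix::colSums(ds$normalized[tm, , drop = FALSE] > 0)
  score <- t_mean - bl_mean
  class <- ifelse(score > tau & detected >= 1, "T",
                  ifelse(bl_mean > t_mean, "Non-T", "unknown"))
  report <- tibble::as_tibble(as.data.frame(table(
    class = factor(class, levels = c("T", "Non-T", "unknown")))))
  names(report) <- c("class", "n")
  keep <- cell_ids(ds)[class == "T"]
  if (!length(keep)) stop("no cells passed the T cell filter")
  tp_log("filter_t_cells: kept %d/%d cells (%d Non-T, %d unknown removed)",
         length(keep), ncol(ds$counts), sum(class == "Non-T"),
         sum(class == "unknown"))
  list(kept = subset_dataset(ds, cells = keep), report = report)
}

#' Map a human dataset into mouse gene space via an ortholog table
#'
#' Genes without any ortholog are dropped. When a human gene maps to several
#' mouse genes (or vice versa) the pair whose upper-cased mouse symbol equals
#' the human symbol is preferred; remaining ambiguities are resolved by
#' lexicographic order of the mouse symbol (logged). When two human genes map
#' to the same mouse gene their counts are summed.
#'
#' @param ds A human [expression_dataset()].
#' @param table Ortholog pairs as returned by [read_ortholog_table()].
#' @return An `expression_dataset` with `species = "mouse"`. Normalized
#'   layers are not carried over: normalize after mapping.
#' @export
map_orthologs <- function(ds, table) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$species != "human") stop("map_orthologs expects a human dataset")
  table <- tibble::as_tibble(table)
  stopifnot(all(c("human_symbol", "mouse_symbol") %in% names(table)))
  tab <- dplyr::filter(table, .data$human_symbol %in% gene_ids(ds))
  if (!nrow(tab)) stop("no query gene has an entry in the ortholog table")

  # one mouse gene per human gene: prefer the case-identical translation,
  # then lexicographic order
  tab <- tab |>
    dplyr::mutate(identical_case =
                    toupper(.data$mouse_symbol) == .data$human_symbol) |>
    dplyr::arrange(.data$human_symbol, dplyr::desc(.data$identical_case),
                   .data$mouse_symbol)
  n_amb <- sum(duplicated(tab$human_symbol))
  tab <- tab[!duplicated(tab$human_symbol), , drop = FALSE]
  if (n_amb > 0) tp_log("map_orthologs: resolved %d ambiguous mappings", n_amb)

  m <- ds$counts[tab$human_symbol, , drop = FALSE]
  rownames(m) <- tab$mouse_symbol
  if (anyDuplicated(tab$mouse_symbol)) {
    # several human genes hitting one mouse gene: sum their counts
    grp <- factor(tab$mouse_symbol, levels = unique(tab$mouse_symbol))
    agg <- Matrix::sparseMatrix(
      i = as.integer(grp), j = seq_along(grp), x = 1,
      dims = c(nlevels(grp), length(grp)),
      dimnames = list(levels(grp), NULL))
    m <- agg %*% m
    m <- as(m, "CsparseMatrix")
  }
  out <- expression_dataset(
    m, ds$cell_meta[, setdiff(names(ds$cell_meta), "empty_cell")],
    species = "mouse")
  tp_log("map_orthologs: %d/%d human genes mapped onto %d mouse genes",
         nrow(tab), nrow(ds$counts), nrow(m))
  out
}

#' Score cells for a gene signature
#'
#' The score is the mean normalized expression over the signature genes
#' present in the dataset, minus (by default) the mean over size-matched
#' random control genes drawn from the same expression-level bins; the
#' control subtraction recenters scores so that unrelated cells sit near
#' zero. With `control = FALSE` the raw signature mean is returned.
#'
#' @param ds Normalized [expression_dataset()].
#' @param signature Character vector of gene symbols.
#' @param control Subtract bin-matched control genes (default `TRUE`).
#' @param n_bins Number of average-expression bins for control matching.
#' @param n_controls Control genes drawn per signature gene.
#' @param seed Seed for the control draw, fixed so scores are reproducible.
#' @return Named numeric vector of per-cell scores.
#' @export
score_signature <- function(ds, signature, control = TRUE, n_bins = 25,
                            n_controls = 100, seed = 1234) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$normalized)) stop("normalize the dataset before scoring")
  sig <- intersect(signature, gene_ids(ds))
  if (!length(sig)) stop("no signature gene present in the dataset")
  if (length(sig) < 0.5 * length(signature)) {
    warning(sprintf("only %d/%d signature genes present in the dataset",
                    length(sig), length(signature)))
  }
  sig_score <- Matrix::colMeans(ds$normalized[sig, , drop = FALSE])
  if (!control) return(sig_score)

  avg <- Matrix::rowMeans(ds$normalized)
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- gene_ids(ds)
  ctrl <- character(0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  for (g in sig) {
    pool <- names(bins)[bins == bins[[g]]]
    ctrl <- c(ctrl, sample(pool, min(n_controls, length(pool)),
                           replace = FALSE))
  }
  ctrl_score <- Matrix::colMeans(ds$normalized[unique(ctrl), , drop = FALSE])
  sig_score - ctrl_score
}
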
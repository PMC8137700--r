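#' Built-in exclusion lists for variable-gene selection
#'
#' Cycling genes ship as a packaged editable list; mitochondrial ("mt-"),
#' ribosomal ("Rps/Rpl") and common non-coding genes are matched by the
#' regular expressions returned by `default_exclude_patterns()`.
#'
#' @return `default_cycling_genes()`: character vector of mouse cell cycle
#'   genes; `default_exclude_patterns()`: character vector of regular
#'   expressions applied to gene symbols.
#' @rdname exclusion_lists
#' @export
default_cycling_genes <- function() {
  path <- system.file("extdata", "cycling_genes_mouse.txt",
                      package = "tcellproj")
  if (nzchar(path)) {
    lines <- readLines(path)
    lines <- trimws(lines[!startsWith(lines, "#")])
    lines[nzchar(lines)]
  } else {
    character(0)
  }
}

#' @rdname exclusion_lists
#' @export
default_exclude_patterns <- function() {
  c("^mt-", "^Rp[sl]", "^Gm[0-9]", "Rik$", "^MT-", "^RP[SL]")
}

#' Select highly variable genes in one dataset
#'
#' Genes are ranked by standardized variance: a loess trend of log variance
#' on log mean expression (computed on raw counts) gives each gene an
#' expected standard deviation; counts are standardized with that expectation
#' (clipped at \eqn{\sqrt{n}}) and the variance of the standardized values is
#' the ranking statistic. Cycling, mitochondrial, ribosomal and non-coding
#' genes, and genes detected in fewer than `min_frac` or more than `max_frac`
#' of cells, are removed before taking the top `n`.
#'
#' @param ds Normalized [expression_dataset()] (counts are used for the
#'   dispersion statistic; the normalized layer must exist so selection runs
#'   on quality-checked data).
#' @param n Number of genes to return (default 600 per dataset).
#' @param exclude_genes Extra gene symbols to exclude; defaults to the
#'   packaged cycling list.
#' @param exclude_patterns Regular expressions for symbol-based exclusion.
#' @param min_frac,max_frac Detection-fraction bounds (defaults 0.001, 0.90).
#' @param loess_span Span of the mean-variance trend fit.
#' @return Character vector of up to `n` genes ordered by decreasing
#'   standardized variance. If fewer than `n` genes are eligible, all of them
#'   are returned with a warning.
#' @export
select_variable_genes <- function(ds, n = 600,
                                  exclude_genes = default_cycling_genes(),
                                  exclude_patterns = default_exclude_patterns(),
                                  min_frac = 0.001, max_frac = 0.90,
                                  loess_span = 0.3) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$normalized)) stop("normalize the dataset first")
  x <- ds$counts
  n_cells <- ncol(x)
  det_frac <- Matrix::rowSums(x > 0) / n_cells
  eligible <- det_frac >= min_frac & det_frac <= max_frac
  eligible <- eligible & !(gene_ids(ds) %in% exclude_genes)
  for (p in exclude_patterns) eligible <- eligible & !grepl(p, gene_ids(ds))

  mu <- Matrix::rowMeans(x)
  # E[x^2] - mu^2, with the n/(n-1) correction, without densifying
  ex2 <- Matrix::rowSums(x^2) / n_cells
  v <- (ex2 - mu^2) * n_cells / (n_cells - 1)
  use <- eligible & v > 0 & mu > 0
  if (!any(use)) stop("no eligible gene with positive variance")

  fit <- stats::loess(log10(v[use]) ~ log10(mu[use]), span = loess_span,
                      degree = 2)
  exp_sd <- sqrt(10^stats::predict(fit))
  clip <- sqrt(n_cells)
  xs <- x[which(use), , drop = FALSE]
  std_var <- standardized_variance(xs, mu[use], exp_sd, clip)
  names(std_var) <- gene_ids(ds)[use]
  ranked <- names(sort(std_var, decreasing = TRUE))
  if (length(ranked) < n) {
    warning(sprintf("only %d eligible genes (requested %d)", length(ranked), n))
    return(ranked)
  }
  ranked[seq_len(n)]
}

# variance of clipped standardized counts, computed sparse-aware:
# zeros standardize to -mu/sd, so each gene's sum over cells splits into the
# nonzero entries plus (n - nnz) copies of the zero term
standardized_variance <- function(x, mu, exp_sd, clip) {
  n <- ncol(x)
  nnz <- Matrix::rowSums(x != 0)
  z0 <- pmax(pmin(-mu / exp_sd, clip), -clip)
  xT <- as(x, "TsparseMatrix")
  zi <- (xT@x - mu[xT@i + 1L]) / exp_sd[xT@i + 1L]
  zi <- pmax(pmin(zi, clip), -clip)
  s1 <- rowsum_by(zi, xT@i + 1L, nrow(x)) + (n - nnz) * z0
  s2 <- rowsum_by(zi^2, xT@i + 1L, nrow(x)) + (n - nnz) * z0^2
  (s2 - s1^2 / n) / (n - 1)
}

rowsum_by <- function(vals, idx, nrow) {
  out <- numeric(nrow)
  if (length(vals)) {
    agg <- rowsum(vals, idx)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Consensus variable genes across datasets
#'
#' Per-dataset variable-gene lists are combined by ranking genes on (1) the
#' number of lists containing the gene, (2) the total cell count of the
#' datasets containing it (so draws favor genes from the largest datasets),
#' (3) the best within-list rank, then (4) lexicographic order; the top `n`
#' genes are returned.
#'
#' @param lists List of per-dataset ordered gene vectors
#'   (from [select_variable_genes()]).
#' @param dataset_sizes Integer cell counts, one per list.
#' @param n Consensus size (default 800).
#' @return Character vector of up to `n` genes.
#' @export
consensus_variable_genes <- function(lists, dataset_sizes, n = 800) {
  stopifnot(length(lists) >= 2, length(dataset_sizes) == length(lists))
  tab <- purrr::imap_dfr(lists, function(genes, i) {
    tibble::tibble(gene = genes, rank = seq_along(genes),
                   size = dataset_sizes[[i]])
  })
  ranked <- tab |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_lists = dplyr::n(), total_cells = sum(.data$size),
                     best_rank = min(.data$rank), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_lists), dplyr::desc(.data$total_cells),
                   .data$best_rank, .data$gene)
  utils::head(ranked$gene, n)
}
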
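#' Subtype composition per condition
#'
#' @param labels Tibble (or data frame) with columns `label` and `condition`
#'   (e.g. the [classify_cells()] output joined with sample metadata), or a
#'   named list of label vectors, one per condition.
#' @param subtypes Optional full subtype set so that absent subtypes are
#'   reported with zero counts; defaults to the labels observed.
#' @return Tibble with `condition`, `subtype`, `n`, `fraction`; fractions sum
#'   to one within each condition.
#' @export
subtype_composition <- function(labels, subtypes = NULL) {
  if (is.list(labels) && !is.data.frame(labels)) {
    labels <- purrr::imap_dfr(labels, function(l, nm)
      tibble::tibble(condition = nm, label = as.character(l)))
  }
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("label", "condition") %in% names(labels)))
  if (any(table(labels$condition) == 0) || nrow(labels) == 0) {
    stop("empty condition in composition input")
  }
  subtypes <- subtypes %||% unique(labels$label)
  out <- labels |>
    dplyr::mutate(subtype = factor(.data$label, levels = subtypes)) |>
    dplyr::count(.data$condition, .data$subtype, .drop = FALSE,
                 name = "n") |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(subtype = as.character(.data$subtype))
  if (any(is.na(out$subtype))) stop("labels outside the supplied subtype set")
  out
}

#' Per-subtype composition fold change between two conditions
#'
#' FC = case fraction / control fraction, reported only for subtypes with at
#' least `min_cells` cells in the two conditions combined; others are listed
#' with the reason for omission. A subtype absent from the control but
#' present in the case is flagged `+Inf` rather than erroring.
#'
#' @param composition Output of [subtype_composition()] containing the two
#'   conditions.
#' @param case,control Condition names.
#' @param min_cells Combined-count threshold (default 50).
#' @return Tibble with `subtype`, `n_case`, `n_control`, `fold_change`,
#'   `status` (`"ok"`, `"infinite"`, or `"omitted_min_cells"`).
#' @export
composition_fold_change <- function(composition, case, control,
                                    min_cells = 50) {
  composition <- tibble::as_tibble(composition)
  stopifnot(all(c(case, control) %in% composition$condition))
  wide <- composition |>
    dplyr::filter(.data$condition %in% c(case, control)) |>
    dplyr::select("condition", "subtype", "n", "fraction") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("n", "fraction"), values_fill = 0)
  n_case <- wide[[paste0("n_", case)]]
  n_ctrl <- wide[[paste0("n_", control)]]
  f_case <- wide[[paste0("fraction_", case)]]
  f_ctrl <- wide[[paste0("fraction_", control)]]
  fc <- ifelse(f_ctrl > 0, f_case / f_ctrl,
               ifelse(f_case > 0, Inf, NA_real_))
  status <- dplyr::case_when(
    n_case + n_ctrl < min_cells ~ "omitted_min_cells",
    is.infinite(fc) ~ "infinite",
    TRUE ~ "ok")
  tibble::tibble(subtype = wide$subtype, n_case = n_case,
                 n_control = n_ctrl,
                 fold_change = ifelse(status == "omitted_min_cells",
                                      NA_real_, fc),
                 status = status)
}

ica_coords_of <- function(x) {
  if (inherits(x, "projection_result")) return(x$ica_coords)
  if (inherits(x, "reference_atlas")) return(x$ica_embeddings)
  as.matrix(x)
}

labels_of <- function(x) {
  if (inherits(x, "projection_result")) {
    stats::setNames(x$predicted_label, rownames(x$ica_coords))
  } else if (inherits(x, "reference_atlas")) {
    x$labels
  } else {
    NULL
  }
}

#' Find independent components that discriminate a query from a baseline
#'
#' For every ICA dimension the query and baseline coordinate distributions
#' are compared with a two-sample Kolmogorov-Smirnov test (or Welch t test);
#' p values are Bonferroni-corrected by the total number of ICA dimensions
#' (not the number of cells or of subset dimensions), and dimensions are
#' ranked by the test statistic. An optional `subset` restricts both sides
#' to cells of one predicted subtype, isolating within-subtype program
#' shifts from composition changes.
#'
#' @param query A `projection_result` (or bare cells x components matrix).
#' @param baseline A `projection_result`, a `reference_atlas`, or a matrix.
#' @param test `"ks"` (default) or `"t"`.
#' @param subset Optional subtype name.
#' @param alpha Significance level on the corrected p value (default 0.05).
#' @return Tibble with `dimension`, `statistic`, `p_value`, `p_adjusted`,
#'   `flagged`, sorted by decreasing statistic.
#' @export
find_discriminant_dimensions <- function(query, baseline,
                                         test = c("ks", "t"), subset = NULL,
                                         alpha = 0.05) {
  test <- match.arg(test)
  q <- ica_coords_of(query)
  b <- ica_coords_of(baseline)
  if (!is.null(subset)) {
    ql <- labels_of(query); bl <- labels_of(baseline)
    if (is.null(ql) || is.null(bl)) {
      stop("subset requires labelled query and baseline")
    }
    q <- q[ql == subset, , drop = FALSE]
    b <- b[bl == subset, , drop = FALSE]
  }
  if (nrow(q) < 10) stop("fewer than 10 cells on the query side")
  if (nrow(b) < 10) stop("fewer than 10 cells on the baseline side")
  stopifnot(ncol(q) == ncol(b))
  n_tests <- ncol(q)
  dims <- colnames(q) %||% paste0("ICA", seq_len(n_tests))
  rows <- purrr::map_dfr(seq_len(n_tests), function(j) {
    ht <- if (test == "ks") {
      suppressWarnings(stats::ks.test(q[, j], b[, j]))
    } else {
      stats::t.test(q[, j], b[, j])
    }
    tibble::tibble(dimension = dims[j],
                   statistic = abs(unname(ht$statistic)),
                   p_value = ht$p.value)
  })
  rows |>
    dplyr::mutate(p_adjusted = pmin(1, n_tests * .data$p_value),
                  flagged = .data$p_adjusted < alpha) |>
    dplyr::arrange(dplyr::desc(.data$statistic))
}

#' Differential expression between two cell groups of one subtype
#'
#' Per-gene Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment on
#' log-normalized expression; the log fold change is the natural log ratio
#' of mean expm1-backtransformed expression with pseudocount 1, positive
#' when higher in `cond_a`. Tests run on the original (pre-correction) query
#' expression; when comparing against the reference, the atlas integrated
#' values of the same subtype are the baseline.
#'
#' @param cond_a A `projection_result` (case).
#' @param cond_b A `projection_result` (control), or a `reference_atlas` to
#'   compare against the reference cells of the same subtype.
#' @param subtype Subtype whose cells enter the test.
#' @param min_cells Minimum cells required on each side (default 25).
#' @param min_logfc,min_detect Reporting filters: absolute logFC above 0.25
#'   and detection in at least 10% of either side, by default.
#' @return Tibble with `gene`, `logFC`, `pct_a`, `pct_b`, `p_value`,
#'   `p_adjusted`, sorted by adjusted p.
#' @export
find_discriminant_genes <- function(cond_a, cond_b, subtype, min_cells = 25,
                                    min_logfc = 0.25, min_detect = 0.10) {
  stopifnot(inherits(cond_a, "projection_result"))
  expr_of <- function(x) {
    if (inherits(x, "projection_result")) {
      m <- x$query_normalized
      keep <- x$predicted_label == subtype
      m[, keep, drop = FALSE]
    } else if (inherits(x, "reference_atlas")) {
      keep <- x$labels == subtype
      x$integrated[, keep, drop = FALSE]
    } else {
      stop("cond_b must be a projection_result or a reference_atlas")
    }
  }
  ma <- expr_of(cond_a); mb <- expr_of(cond_b)
  if (ncol(ma) < min_cells) stop("fewer than min_cells cells in cond_a")
  if (ncol(mb) < min_cells) stop("fewer than min_cells cells on the baseline side")
  genes <- intersect(rownames(ma), rownames(mb))
  ma <- as.matrix(ma[genes, , drop = FALSE])
  mb <- as.matrix(mb[genes, , drop = FALSE])
  pct_a <- rowMeans(ma > 0); pct_b <- rowMeans(mb > 0)
  mean_a <- rowMeans(expm1(ma)); mean_b <- rowMeans(expm1(mb))
  logfc <- log((mean_a + 1) / (mean_b + 1))
  keep <- abs(logfc) > min_logfc & pmax(pct_a, pct_b) >= min_detect
  if (!any(keep)) {
    return(tibble::tibble(gene = character(), logFC = numeric(),
                          pct_a = numeric(), pct_b = numeric(),
                          p_value = numeric(), p_adjusted = numeric()))
  }
  idx <- which(keep)
  p <- vapply(idx, function(g) {
    suppressWarnings(stats::wilcox.test(ma[g, ], mb[g, ]))$p.value
  }, numeric(1))
  tibble::tibble(gene = genes[idx], logFC = logfc[idx],
                 pct_a = pct_a[idx], pct_b = pct_b[idx],
                 p_value = p,
                 p_adjusted = stats::p.adjust(p, "BH")) |>
    dplyr::arrange(.data$p_adjusted, .data$p_value)
}

#' Cross-study marker consensus and clustered expression profiles
#'
#' Pools per-study per-subtype differential-expression results: a gene
#' enters the panel when it is differentially expressed for some subtype in
#' at least `min_studies` studies; each gene is attributed to the subtype
#' with the most supporting studies (ties towards smaller mean adjusted p),
#' at most `max_per_subtype` genes per subtype, intersected with the atlas
#' variable genes. The per-(gene, subtype-study) mean expression matrix is
#' z-scored by row and rows and columns are clustered with Ward linkage on
#' Euclidean distance; the column cluster assignment at the number of
#' subtypes supports assessing whether profiles group by subtype rather than
#' by study.
#'
#' @param de_tables Tibble with columns `study`, `subtype`, `gene`,
#'   `p_adjusted` and `n_cells` (cells supporting that subtype-study side);
#'   one row per DE gene call.
#' @param expr_means Tibble with columns `study`, `subtype`, `gene`,
#'   `mean_expr` giving mean integrated expression per combination.
#' @param atlas_var_genes Atlas variable genes used to intersect the panel.
#' @param min_studies,max_per_subtype,min_cells Defaults 4, 25, 50.
#' @return List with `panel` (tibble `gene`, `subtype`, `n_studies`),
#'   `profile` (z-scored matrix, genes x subtype-study columns),
#'   `row_hclust`, `col_hclust`, and `col_clusters` (cut at the number of
#'   panel subtypes).
#' @export
marker_consensus <- function(de_tables, expr_means, atlas_var_genes,
                             min_studies = 4, max_per_subtype = 25,
                             min_cells = 50) {
  de_tables <- tibble::as_tibble(de_tables) |>
    dplyr::filter(.data$n_cells >= min_cells) |>
    dplyr::arrange(.data$study, .data$subtype, .data$gene)
  support <- de_tables |>
    dplyr::distinct(.data$gene, .data$subtype, .data$study,
                    .keep_all = TRUE) |>
    dplyr::group_by(.data$gene, .data$subtype) |>
    dplyr::summarise(n_studies = dplyr::n(),
                     mean_padj = mean(.data$p_adjusted), .groups = "drop")
  # attribute each gene to its best-supported subtype
  attributed <- support |>
    dplyr::group_by(.data$gene) |>
    dplyr::arrange(dplyr::desc(.data$n_studies), .data$mean_padj,
                   .data$subtype, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_studies >= min_studies,
                  .data$gene %in% atlas_var_genes)
  panel <- attributed |>
    dplyr::group_by(.data$subtype) |>
    dplyr::arrange(dplyr::desc(.data$n_studies), .data$mean_padj,
                   .data$gene, .by_group = TRUE) |>
    dplyr::slice_head(n = max_per_subtype) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subtype, .data$gene) |>
    dplyr::select("gene", "subtype", "n_studies")
  if (nrow(panel) == 0) {
    stop(sprintf(paste0("empty marker panel: %d genes reached min_studies=%d ",
                        "before the atlas-gene intersection"),
                 sum(support$n_studies >= min_studies), min_studies))
  }
  combos <- de_tables |>
    dplyr::distinct(.data$study, .data$subtype) |>
    dplyr::arrange(.data$subtype, .data$study) |>
    dplyr::mutate(column = paste(.data$subtype, .data$study, sep = "."))
  expr_means <- tibble::as_tibble(expr_means) |>
    dplyr::inner_join(combos, by = c("study", "subtype")) |>
    dplyr::filter(.data$gene %in% panel$gene)
  profile <- expr_means |>
    dplyr::select("gene", "column", "mean_expr") |>
    tidyr::pivot_wider(names_from = "column", values_from = "mean_expr",
                       values_fill = 0)
  mat <- as.matrix(profile[, -1])
  rownames(mat) <- profile$gene
  mat <- mat[panel$gene[panel$gene %in% rownames(mat)], combos$column,
             drop = FALSE]
  # row z-score; constant rows stay at zero
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  sdv[sdv < 1e-12] <- 1
  z <- (mat - mu) / sdv
  row_hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  col_hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  k <- length(unique(panel$subtype))
  col_clusters <- stats::cutree(col_hc, k = max(1, k))
  list(panel = panel, profile = z, row_hclust = row_hc, col_hclust = col_hc,
       col_clusters = col_clusters)
}

#' Rescale average expression per gene by its maximum over subtypes
#'
#' Each gene row is divided by its maximum over the selected subtypes so
#' profiles of differently-expressed genes become comparable; all-zero rows
#' stay zero.
#'
#' @param avg_expression Genes x subtypes matrix of non-negative means.
#' @param subtypes Optional subset (and order) of subtype columns.
#' @return Matrix of the same genes with values in \[0, 1\].
#' @export
normalized_marker_profile <- function(avg_expression, subtypes = NULL) {
  m <- as.matrix(avg_expression)
  if (any(m < 0)) stop("average expression must be non-negative")
  if (!is.null(subtypes)) m <- m[, subtypes, drop = FALSE]
  mx <- apply(m, 1, max)
  mx[mx == 0] <- 1
  m / mx
}
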
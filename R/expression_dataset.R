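#' Construct an expression dataset
#'
#' The basic container of the package: a sparse genes-by-cells count matrix
#' together with per-cell metadata. All matrices in this package are stored
#' and returned gene-major (rows are genes, columns are cells); every function
#' that accepts or returns a matrix states this orientation explicitly.
#'
#' @param counts Non-negative numeric matrix, genes x cells. Dense matrices
#'   are converted to sparse `dgCMatrix`. Row names are gene identifiers,
#'   column names are cell barcodes; both must be unique and non-empty.
#' @param cell_meta Optional data frame of per-cell metadata with one row per
#'   cell. Recognised columns are `sample_id`, `dataset_id`, `condition` and
#'   `clonotype_id`; extra columns are kept. A `cell_id` column is added (or
#'   checked) against the matrix column names.
#' @param species Either `"mouse"` or `"human"`.
#' @param normalized Optional matrix of log-normalized values with the exact
#'   shape and dimnames of `counts` (usually filled in by
#'   [normalize_counts()]).
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `counts`, `normalized` (possibly `NULL`), `cell_meta` (a tibble) and
#'   `species`. Cells whose total count is zero are flagged in the
#'   `empty_cell` metadata column but are not dropped; [normalize_counts()]
#'   removes them with a logged count.
#' @export
expression_dataset <- function(counts, cell_meta = NULL, species = "mouse",
                               normalized = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!inherits(counts, "dgCMatrix")) {
    counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry gene row names and cell column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in `counts`")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids in `counts`")
  if (any(counts@x < 0)) stop("`counts` must be non-negative")
  species <- match.arg(species, c("mouse", "human"))

  meta <- tibble::tibble(cell_id = colnames(counts))
  if (!is.null(cell_meta)) {
    cell_meta <- tibble::as_tibble(cell_meta)
    if (!"cell_id" %in% names(cell_meta)) {
      if (nrow(cell_meta) != ncol(counts)) {
        stop("`cell_meta` must have one row per cell")
      }
      cell_meta$cell_id <- colnames(counts)
    }
    if (!all(meta$cell_id %in% cell_meta$cell_id)) {
      stop("every cell in `counts` needs a `cell_meta` row keyed by cell_id")
    }
    meta <- dplyr::left_join(meta, cell_meta, by = "cell_id")
  }
  meta$empty_cell <- unname(Matrix::colSums(counts) == 0)

  if (!is.null(normalized)) {
    stopifnot(identical(dim(normalized), dim(counts)),
              identical(dimnames(normalized), dimnames(counts)))
    if (!inherits(normalized, "dgCMatrix")) {
      normalized <- as(as(as(normalized, "dMatrix"), "generalMatrix"),
                       "CsparseMatrix")
    }
  }

  structure(
    list(counts = counts, normalized = normalized, cell_meta = meta,
         species = species),
    class = "expression_dataset"
  )
}

#' @method print expression_dataset
#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %d genes x %d cells (%s)%s\n",
    nrow(x$counts), ncol(x$counts), x$species,
    if (is.null(x$normalized)) ", raw counts" else ", normalized layer present"
  ))
  extra <- setdiff(names(x$cell_meta), c("cell_id", "empty_cell"))
  if (length(extra)) cat("  cell_meta:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$counts)

gene_ids <- function(ds) rownames(ds$counts)
cell_ids <- function(ds) colnames(ds$counts)

#' Subset an expression dataset by genes and/or cells
#'
#' @param ds An `expression_dataset`.
#' @param genes,cells Character vectors of identifiers to keep (in the given
#'   order); `NULL` keeps everything.
#' @return A new `expression_dataset`.
#' @export
subset_dataset <- function(ds, genes = NULL, cells = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  genes <- genes %||% gene_ids(ds)
  cells <- cells %||% cell_ids(ds)
  stopifnot(all(genes %in% gene_ids(ds)), all(cells %in% cell_ids(ds)))
  out <- ds
  out$counts <- ds$counts[genes, cells, drop = FALSE]
  if (!is.null(ds$normalized)) {
    out$normalized <- ds$normalized[genes, cells, drop = FALSE]
  }
  out$cell_meta <- ds$cell_meta[match(cells, ds$cell_meta$cell_id), ,
                                drop = FALSE]
  out
}

#' Combine datasets column-wise over the union of their genes
#'
#' Genes absent from a dataset are treated as zero. Cell ids must be unique
#' across datasets (prefix them with a sample tag beforehand if needed).
#'
#' @param ds_list List of `expression_dataset` objects of one species.
#' @param layer Which layer to merge: `"counts"` or `"normalized"`.
#' @return An `expression_dataset` carrying the merged layer as counts when
#'   `layer = "counts"`, or with both layers when all inputs are normalized.
#' @export
merge_datasets <- function(ds_list, layer = c("counts", "normalized")) {
  layer <- match.arg(layer)
  stopifnot(length(ds_list) >= 1,
            all(vapply(ds_list, inherits, TRUE, "expression_dataset")))
  sp <- unique(vapply(ds_list, function(d) d$species, ""))
  if (length(sp) != 1) stop("cannot merge datasets of different species")
  all_genes <- Reduce(union, lapply(ds_list, gene_ids))
  pad <- function(m) {
    missing <- setdiff(all_genes, rownames(m))
    if (length(missing)) {
      fill <- Matrix::sparseMatrix(i = integer(), j = integer(),
                                   dims = c(length(missing), ncol(m)),
                                   dimnames = list(missing, colnames(m)))
      m <- rbind(m, fill)
    }
    m[all_genes, , drop = FALSE]
  }
  counts <- do.call(cbind, lapply(ds_list, function(d) pad(d$counts)))
  meta <- dplyr::bind_rows(lapply(ds_list, function(d) d$cell_meta))
  if (anyDuplicated(colnames(counts))) {
    stop("cell ids collide across datasets; disambiguate before merging")
  }
  out <- expression_dataset(counts, meta, species = sp)
  if (layer == "normalized" || all(!vapply(ds_list, function(d)
    is.null(d$normalized), TRUE))) {
    norm_ok <- all(!vapply(ds_list, function(d) is.null(d$normalized), TRUE))
    if (layer == "normalized" && !norm_ok) {
      stop("not all datasets carry a normalized layer")
    }
    if (norm_ok) {
      out$normalized <- do.call(cbind,
                                lapply(ds_list, function(d) pad(d$normalized)))
    }
  }
  out
}
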
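#' Read a gene-by-cell count matrix
#'
#' Supports CellRanger-style Matrix Market triplet directories
#' (`matrix.mtx` + `features.tsv`/`genes.tsv` + `barcodes.tsv`, optionally
#' gzipped) and dense CSV/TSV files whose first column holds gene ids and
#' whose header row holds cell ids. The matrix is loaded genes x cells.
#'
#' Duplicate gene symbols are disambiguated by suffixing `.1`, `.2`, ... in
#' file order. Cells with zero total counts are kept but flagged in
#' `cell_meta$empty_cell`.
#'
#' @param path Directory (for `format = "mtx10x"`) or file path.
#' @param format One of `"mtx10x"`, `"csv"`, `"tsv"`.
#' @param species `"mouse"` or `"human"`.
#' @param sample_id,dataset_id Optional labels recorded per cell.
#' @return An [expression_dataset()].
#' @export
read_counts <- function(path, format = c("mtx10x", "csv", "tsv"),
                        species = "mouse", sample_id = NULL,
                        dataset_id = NULL) {
  format <- match.arg(format)
  if (format == "mtx10x") {
    find_one <- function(cands, what) {
      for (f in cands) {
        p <- file.path(path, f)
        if (file.exists(p)) return(p)
      }
      stop(sprintf("mtx10x directory '%s' is missing the %s file (looked for %s)",
                   path, what, paste(cands, collapse = ", ")))
    }
    if (!dir.exists(path)) stop(sprintf("'%s' is not a directory", path))
    mtx <- find_one(c("matrix.mtx", "matrix.mtx.gz"), "matrix")
    feat <- find_one(c("features.tsv", "features.tsv.gz", "genes.tsv",
                       "genes.tsv.gz"), "gene list")
    bc <- find_one(c("barcodes.tsv", "barcodes.tsv.gz"), "barcode")
    m <- as(Matrix::readMM(mtx), "CsparseMatrix")
    ft <- utils::read.table(feat, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    # CellRanger features.tsv: id, symbol, type; single-column lists also ok
    genes <- if (ncol(ft) >= 2) ft[[2]] else ft[[1]]
    cells <- readLines(bc)
    if (length(genes) != nrow(m)) {
      stop(sprintf("gene list length (%d) does not match matrix rows (%d)",
                   length(genes), nrow(m)))
    }
    if (length(cells) != ncol(m)) {
      stop(sprintf("barcode list length (%d) does not match matrix columns (%d)",
                   length(cells), ncol(m)))
    }
    dimnames(m) <- list(make_unique_genes(genes), cells)
  } else {
    sep <- if (format == "csv") "," else "\t"
    raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                             check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(raw[[1]])
    num <- raw[, -1, drop = FALSE]
    bad <- which(!vapply(num, is.numeric, TRUE))
    if (length(bad)) {
      for (j in bad) {
        val <- suppressWarnings(as.numeric(num[[j]]))
        if (anyNA(val)) {
          i <- which(is.na(val))[1]
          stop(sprintf(
            "non-numeric entry '%s' at row %d, column '%s' of %s",
            num[[j]][i], i, names(num)[j], path))
        }
        num[[j]] <- val
      }
    }
    m <- as(as.matrix(num), "CsparseMatrix")
    dimnames(m) <- list(make_unique_genes(genes), colnames(num))
  }
  meta <- tibble::tibble(cell_id = colnames(m))
  if (!is.null(sample_id)) meta$sample_id <- sample_id
  if (!is.null(dataset_id)) meta$dataset_id <- dataset_id
  ds <- expression_dataset(m, meta, species = species)
  n_empty <- sum(ds$cell_meta$empty_cell)
  if (n_empty > 0) tp_log("read_counts: %d cells with zero counts flagged", n_empty)
  ds
}

make_unique_genes <- function(genes) {
  genes <- as.character(genes)
  if (!anyDuplicated(genes)) return(genes)
  ave(genes, genes, FUN = function(g) {
    if (length(g) == 1) g else c(g[1], paste0(g[-1], ".", seq_len(length(g) - 1)))
  })
}

#' Write a dataset's counts as a Matrix Market triplet directory
#'
#' Emits `matrix.mtx`, `features.tsv` and `barcodes.tsv` so the output can be
#' re-read with [read_counts()].
#'
#' @param ds An `expression_dataset`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_counts_mtx <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(ds$counts, file.path(path, "matrix.mtx"))
  utils::write.table(
    data.frame(id = gene_ids(ds), symbol = gene_ids(ds),
               type = "Gene Expression"),
    file.path(path, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(cell_ids(ds), file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Read a GMT gene-signature file
#'
#' @param path Tab-delimited GMT file: signature name, description, then gene
#'   symbols. The description column is discarded and blank gene fields are
#'   dropped.
#' @return A named list of character vectors (a signature set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
    }
    sigs[[fields[1]]] <- fields[-(1:2)]
  }
  if (anyDuplicated(names(sigs))) stop("duplicate signature names in GMT")
  sigs
}

#' Read a two-column human-to-mouse ortholog table
#'
#' @param path TSV with columns `human_symbol` and `mouse_symbol`; lines
#'   starting with `#` are comments. A packaged synthetic demonstration
#'   subset is available via
#'   `system.file("extdata", "orthologs_synthetic_subset.tsv", package = "tcellproj")`.
#' @return A tibble with columns `human_symbol`, `mouse_symbol`.
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("ortholog table needs two tab-separated columns")
  names(tab)[1:2] <- c("human_symbol", "mouse_symbol")
  tibble::as_tibble(tab[, 1:2])
}

#' Read a cell-to-clonotype assignment table
#'
#' @param path TSV with columns `cell_id`, `clonotype_id` and optionally
#'   `sample_id`.
#' @return A tibble.
#' @export
read_clonotype_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("cell_id", "clonotype_id")
  if (!all(need %in% names(tab))) {
    stop("clonotype table needs columns cell_id and clonotype_id")
  }
  tibble::as_tibble(tab)
}
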
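#' Build a cells-by-genes count matrix container
#'
#' Bundles a raw non-negative integer count matrix with per-gene flags
#' (cell-surface molecule, mitochondrial, ERCC spike-in, neuronal marker)
#' and per-cell metadata (subtype label). This is the object every QC and
#' profiling step consumes; counts are held sparse.
#'
#' @param counts cells x genes matrix of non-negative integers (base or
#'   `Matrix` sparse). Row names are cell ids, column names gene ids; if
#'   absent they are synthesised.
#' @param genes tibble/data.frame with columns `gene_id` and optionally
#'   logical `is_csm`, `is_mito`, `is_ercc`, `is_marker`. Missing flag
#'   columns are inferred from gene-id prefixes (`mt:` mitochondrial,
#'   `ERCC-` spike-in) and default to `FALSE` otherwise.
#' @param cells tibble/data.frame with columns `cell_id` and optionally
#'   `subtype`.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (dgCMatrix, cells x genes), `genes` (tibble) and `cells`
#'   (tibble).
#' @export
count_matrix <- function(counts, genes = NULL, cells = NULL) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (any(counts@x < 0)) abort("count matrix contains negative entries")
  if (any(counts@x != round(counts@x))) abort("count matrix contains non-integer entries")
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("g%04d", seq_len(ncol(counts)))
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("cell%04d", seq_len(nrow(counts)))

  if (is.null(genes)) genes <- tibble(gene_id = colnames(counts))
  genes <- as_tibble(genes)
  if (!"gene_id" %in% names(genes)) abort("`genes` needs a gene_id column")
  if (anyDuplicated(genes$gene_id)) abort("gene ids must be unique")
  if (!identical(genes$gene_id, colnames(counts))) {
    if (!setequal(genes$gene_id, colnames(counts)))
      abort("`genes$gene_id` does not match the count matrix columns")
    genes <- genes[match(colnames(counts), genes$gene_id), ]
  }
  if (!"is_mito" %in% names(genes)) genes$is_mito <- startsWith(genes$gene_id, "mt:")
  if (!"is_ercc" %in% names(genes)) genes$is_ercc <- startsWith(genes$gene_id, "ERCC-")
  if (!"is_csm" %in% names(genes)) genes$is_csm <- FALSE
  if (!"is_marker" %in% names(genes)) genes$is_marker <- FALSE

  if (is.null(cells)) cells <- tibble(cell_id = rownames(counts))
  cells <- as_tibble(cells)
  if (!"cell_id" %in% names(cells)) abort("`cells` needs a cell_id column")
  if (anyDuplicated(cells$cell_id)) abort("cell ids must be unique")
  if (!identical(cells$cell_id, rownames(counts))) {
    if (!setequal(cells$cell_id, rownames(counts)))
      abort("`cells$cell_id` does not match the count matrix rows")
    cells <- cells[match(rownames(counts), cells$cell_id), ]
  }
  if (!"subtype" %in% names(cells)) cells$subtype <- NA_character_

  structure(list(counts = counts, genes = genes, cells = cells),
            class = "count_matrix")
}

#' @method print count_matrix
#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  CSM %d | mito %d | ERCC %d | marker %d genes\n",
              sum(x$genes$is_csm), sum(x$genes$is_mito),
              sum(x$genes$is_ercc), sum(x$genes$is_marker)))
  n_lab <- sum(!is.na(x$cells$subtype))
  cat(sprintf("  %d labelled cells, %d subtypes\n", n_lab,
              dplyr::n_distinct(x$cells$subtype[!is.na(x$cells$subtype)])))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by cell ids
#' @param m a [count_matrix()]
#' @param cell_ids character vector of cell ids to keep (order preserved
#'   as in `m`)
#' @return a `count_matrix`
#' @keywords internal
subset_cells <- function(m, cell_ids) {
  keep <- m$cells$cell_id %in% cell_ids
  if (!any(keep)) abort("no cells left after filtering")
  count_matrix(m$counts[keep, , drop = FALSE], m$genes, m$cells[keep, ])
}

#' Per-cell library sizes
#' @param m a [count_matrix()]
#' @param exclude_ercc drop ERCC spike-ins from the total
#' @return named numeric vector, one entry per cell
#' @export
library_sizes <- function(m, exclude_ercc = FALSE) {
  keep <- if (exclude_ercc) !m$genes$is_ercc else rep(TRUE, ncol(m$counts))
  setNames(Matrix::rowSums(m$counts[, keep, drop = FALSE]), m$cells$cell_id)
}

#' Write / read a count matrix as MatrixMarket plus TSV metadata
#'
#' The on-disk layout is `matrix.mtx` (genes stored as columns),
#' `genes.tsv` (gene_id + flag columns) and `cells.tsv` (cell_id,
#' subtype), matching the common sparse single-cell exchange format.
#'
#' @param m a [count_matrix()]
#' @param dir directory to create/populate
#' @return `write_counts_mtx` the directory, invisibly; `read_counts_mtx`
#'   a `count_matrix`.
#' @export
write_counts_mtx <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(m$genes, file.path(dir, "genes.tsv"))
  readr::write_tsv(m$cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`
#' @export
read_counts_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"), show_col_types = FALSE)
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"), show_col_types = FALSE)
  rownames(counts) <- cells$cell_id
  colnames(counts) <- genes$gene_id
  count_matrix(counts, genes, cells)
}

#' Read a dense CSV count table (cells as rows, genes as columns)
#'
#' First column must hold cell ids; remaining columns are gene counts.
#' Gene flags are inferred from id prefixes unless a `genes` table is
#' supplied.
#'
#' @param path CSV file
#' @param genes optional gene metadata tibble (see [count_matrix()])
#' @param cells optional cell metadata tibble
#' @return a `count_matrix`
#' @export
read_counts_csv <- function(path, genes = NULL, cells = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- ids
  count_matrix(mat, genes, cells)
}
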
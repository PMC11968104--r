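#' Single-cell cohort container
#'
#' A `cohort` bundles a sparse gene x cell integer count matrix with its two
#' metadata tables: one row per cell (`cell_id`, `genotype`, `run`, `cluster`)
#' and one row per gene (`gene`, logical `mito` flag). All pipeline stages
#' take and return this container or plain tibbles derived from it.
#'
#' @param counts sparse or dense numeric matrix, genes in rows, cells in
#'   columns; coerced to [Matrix::dgCMatrix-class].
#' @param cells data frame with columns `cell_id`, `genotype`, `run`,
#'   `cluster`; one row per column of `counts`.
#' @param genes data frame with columns `gene` and logical `mito`; one row
#'   per row of `counts`.
#' @return An object of class `cohort`.
#' @export
cohort <- function(counts, cells, genes) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "dMatrix")
  cells <- tibble::as_tibble(cells)
  genes <- tibble::as_tibble(genes)
  assert_that(all(c("cell_id", "genotype", "run", "cluster") %in% names(cells)),
              "`cells` needs columns cell_id, genotype, run, cluster")
  assert_that(all(c("gene", "mito") %in% names(genes)),
              "`genes` needs columns gene and mito")
  assert_that(ncol(counts) == nrow(cells), "one `cells` row per count column required")
  assert_that(nrow(counts) == nrow(genes), "one `genes` row per count row required")
  dimnames(counts) <- list(genes$gene, cells$cell_id)
  structure(list(counts = counts, cells = cells, genes = genes), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d genes x %d cells | %d genotypes, %d clusters, %d runs\n",
              nrow(x$counts), ncol(x$counts),
              dplyr::n_distinct(x$cells$genotype),
              dplyr::n_distinct(x$cells$cluster),
              dplyr::n_distinct(x$cells$run)))
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$counts)

# Subset a cohort to a logical/integer cell index, keeping genes intact.
subset_cells <- function(x, idx) {
  cohort(x$counts[, idx, drop = FALSE], x$cells[idx, , drop = FALSE], x$genes)
}

#' Per-cell quality metrics
#'
#' @param x a [cohort()].
#' @return The cell table with `n_genes` (genes detected), `total_counts`
#'   (UMIs) and `mito_pct` (percent of counts in mitochondrial genes,
#'   computed on raw counts) appended.
#' @export
cell_metrics <- function(x) {
  stopifnot(inherits(x, "cohort"))
  tot <- Matrix::colSums(x$counts)
  ngene <- Matrix::colSums(x$counts > 0)
  mito <- x$genes$mito
  mito_counts <- if (any(mito)) Matrix::colSums(x$counts[mito, , drop = FALSE]) else rep(0, ncol(x$counts))
  dplyr::mutate(x$cells,
                n_genes = as.integer(ngene),
                total_counts = as.numeric(tot),
                mito_pct = ifelse(tot > 0, 100 * mito_counts / tot, 0))
}

#' Write a cohort to disk as Matrix Market plus TSV sidecars
#'
#' Writes `matrix.mtx` (cells x genes, the scanpy orientation), `cells.tsv`
#' and `genes.tsv`, plus `truth.json` when a ground-truth record is given.
#'
#' @param x a [cohort()].
#' @param dir output directory, created if absent.
#' @param truth optional synthetic-truth list as returned by
#'   [generate_cohort()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir, truth = NULL) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  readr::write_tsv(x$cells, file.path(dir, "cells.tsv"))
  readr::write_tsv(x$genes, file.path(dir, "genes.tsv"))
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `matrix.mtx`, `cells.tsv`, `genes.tsv`.
#' @return A [cohort()].
#' @export
read_cohort <- function(dir) {
  m <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"), show_col_types = FALSE)
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"), show_col_types = FALSE)
  genes$mito <- as.logical(genes$mito)
  cohort(m, cells, genes)
}
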
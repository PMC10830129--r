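#' Read an expression dataset from Matrix Market files
#'
#' Expects a directory with `matrix.mtx` (genes x cells, raw counts),
#' `genes.tsv` (one gene id per line, or a `gene_id` column) and
#' `cells.tsv` (columns `cell_id`, `tissue`, `cell_type`, `sample`).
#' Gzipped variants (`.gz`) are accepted.
#'
#' @param dir Directory containing the three files.
#' @param species Species label for the dataset.
#'
#' @return An [expression_dataset()].
#' @export
read_expression_mtx <- function(dir, species = "unknown") {
  find1 <- function(base) {
    for (f in file.path(dir, c(base, paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    abort(sprintf("no '%s' (or .gz) in %s", base, dir))
  }
  counts <- Matrix::readMM(find1("matrix.mtx"))
  genes <- readr::read_tsv(find1("genes.tsv"), show_col_types = FALSE)
  gene_ids <- if ("gene_id" %in% names(genes)) genes$gene_id else genes[[1]]
  cells <- readr::read_tsv(find1("cells.tsv"), show_col_types = FALSE)
  dimnames(counts) <- list(gene_ids, cells$cell_id)
  expression_dataset(counts, cells, species = species)
}

#' Read an expression dataset from a dense TSV
#'
#' @param counts_tsv TSV of raw counts, genes in rows (first column
#'   `gene_id`), cells in columns.
#' @param cells_tsv TSV with columns `cell_id`, `tissue`, `cell_type`,
#'   `sample`.
#' @inheritParams read_expression_mtx
#'
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(counts_tsv, cells_tsv, species = "unknown") {
  tab <- readr::read_tsv(counts_tsv, show_col_types = FALSE)
  counts <- as.matrix(tab[, -1])
  rownames(counts) <- tab[[1]]
  cells <- readr::read_tsv(cells_tsv, show_col_types = FALSE)
  expression_dataset(counts, cells, species = species)
}

#' Write an expression dataset as Matrix Market + TSVs
#'
#' @param data An [expression_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression_mtx <- function(data, dir) {
  stopifnot(inherits(data, "expr_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(as.matrix(data$counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(gene_id = rownames(data$counts)),
                   file.path(dir, "genes.tsv"))
  readr::write_tsv(data$cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Write and read per-tissue preferential-expression tables
#'
#' The on-disk form is one long TSV per tissue (`gene`, `cell_type`, `z`),
#' named `preferential_expression_<tissue>.tsv`.
#'
#' @param pref Named list of `pref_expr` objects ([preferential_expression_by_tissue()]).
#' @param dir Output directory.
#' @return The written file paths, invisibly.
#' @export
write_preferential_expression <- function(pref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- imap(pref, function(p, ts) {
    path <- file.path(dir, sprintf("preferential_expression_%s.tsv", ts))
    readr::write_tsv(tidy(p)[, c("gene", "cell_type", "z")], path)
    path
  })
  invisible(unlist(paths))
}

#' @rdname write_preferential_expression
#' @param dir Directory holding `preferential_expression_*.tsv` files.
#' @export
read_preferential_expression <- function(dir) {
  files <- sort(list.files(dir, "^preferential_expression_.*\\.tsv$",
                           full.names = TRUE), method = "radix")
  if (length(files) == 0) abort(sprintf("no preferential_expression_*.tsv in %s", dir))
  out <- lapply(files, function(f) {
    ts <- sub("^preferential_expression_(.*)\\.tsv$", "\\1", basename(f))
    long <- readr::read_tsv(f, show_col_types = FALSE)
    z <- long |>
      tidyr::pivot_wider(names_from = "cell_type", values_from = "z") |>
      as.data.frame()
    rownames(z) <- z$gene
    z$gene <- NULL
    structure(
      list(tissue = ts, z = as.matrix(z), ddof = NA_integer_,
           dropped_zero_sd = character()),
      class = "pref_expr"
    )
  })
  names(out) <- vapply(out, function(p) p$tissue, character(1))
  out
}

#' Write a PrEDiCT result table
#'
#' @param result A `predict_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_predict_result <- function(result, path) {
  readr::write_tsv(tidy(result), path)
  invisible(path)
}
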
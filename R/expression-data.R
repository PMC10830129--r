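#' Construct a single-species expression dataset
#'
#' Bundles a raw UMI count matrix with its per-cell annotations. Counts are
#' oriented genes x cells; the annotation table must carry one row per cell,
#' aligned with the columns of `counts`.
#'
#' @param counts Non-negative numeric matrix (base or `Matrix` sparse),
#'   genes in rows, cells in columns. Row names are gene identifiers and
#'   must be unique; column names are cell identifiers.
#' @param cells Data frame with one row per cell and columns `cell_id`,
#'   `tissue`, `cell_type`, `sample`.
#' @param species Species label stored with the dataset.
#'
#' @return An object of class `expr_dataset`: a list with elements `counts`,
#'   `cells` (tibble) and `species`.
#' @export
expression_dataset <- function(counts, cells, species = "unknown") {
  cells <- as_tibble(cells)
  required <- c("cell_id", "tissue", "cell_type", "sample")
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0) {
    abort(paste0("`cells` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene row names and cell column names")
  }
  if (anyDuplicated(rownames(counts)) > 0) {
    abort("gene identifiers (rownames of `counts`) must be unique")
  }
  if (ncol(counts) != nrow(cells) || !identical(colnames(counts), cells$cell_id)) {
    abort("columns of `counts` must align with `cells$cell_id`")
  }
  if (min(counts) < 0) {
    abort("`counts` must be non-negative")
  }
  structure(
    list(counts = counts, cells = cells, species = species),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf(
    "<expr_dataset> %s: %d genes x %d cells, %d tissue(s), %d cell type(s)\n",
    x$species, nrow(x$counts), ncol(x$counts),
    dplyr::n_distinct(x$cells$tissue),
    dplyr::n_distinct(paste(x$cells$tissue, x$cells$cell_type))
  ))
  invisible(x)
}

#' Library-size normalize raw counts
#'
#' Per cell, counts are scaled to a common library size and log-transformed:
#' `log1p(count * scale / cell_total)`. This is the standard cell-wise
#' log-normalization used by single-cell toolkits.
#'
#' @param data An [expression_dataset()], or a raw genes x cells count matrix.
#' @param scale Library-size scale factor (default `1e4`).
#' @param drop_zero_cells If `TRUE`, cells with zero total counts are dropped
#'   with a message; if `FALSE` (default) such cells raise an error naming
#'   them.
#'
#' @return A normalized matrix of the same orientation (genes x cells). When
#'   `data` is an `expr_dataset` the result carries a `cells` attribute with
#'   the (possibly subset) annotation tibble.
#' @export
normalize_counts <- function(data, scale = 1e4, drop_zero_cells = FALSE) {
  counts <- if (inherits(data, "expr_dataset")) data$counts else data
  if (min(counts) < 0) abort("counts must be non-negative")
  if (scale <= 0) abort("`scale` must be positive")
  totals <- Matrix::colSums(counts)
  zero <- totals == 0
  cells <- if (inherits(data, "expr_dataset")) data$cells else NULL
  if (any(zero)) {
    bad <- colnames(counts)[zero]
    if (drop_zero_cells) {
      inform(sprintf("dropping %d zero-count cell(s)", length(bad)))
      counts <- counts[, !zero, drop = FALSE]
      totals <- totals[!zero]
      if (!is.null(cells)) cells <- cells[!zero, , drop = FALSE]
    } else {
      abort(paste0(
        "cell(s) with zero total counts: ",
        paste(head(bad, 5), collapse = ", "),
        if (length(bad) > 5) ", ..." else ""
      ))
    }
  }
  norm <- as.matrix(counts)
  norm <- log1p(sweep(norm, 2, totals / scale, "/"))
  if (!is.null(cells)) attr(norm, "cells") <- cells
  norm
}

#' Filter to expressed genes
#'
#' A gene is retained when, in at least one cell type, at least a fraction
#' `min_frac` of that type's cells have normalized expression at or above
#' `min_value` (both comparisons inclusive).
#'
#' @param norm Normalized genes x cells matrix ([normalize_counts()]).
#' @param cell_type Character vector of cell-type labels, one per column of
#'   `norm`.
#' @param min_value Minimum normalized value counted as expression
#'   (default 0.05).
#' @param min_frac Minimum fraction of a cell type's cells (default 0.10).
#'
#' @return Character vector of retained gene identifiers, in the row order
#'   of `norm`.
#' @export
filter_expressed_genes <- function(norm, cell_type, min_value = 0.05, min_frac = 0.10) {
  if (length(cell_type) != ncol(norm)) {
    abort("`cell_type` must have one label per column of `norm`")
  }
  types <- unique(cell_type)
  keep <- rep(FALSE, nrow(norm))
  for (ct in types) {
    idx <- which(cell_type == ct)
    if (length(idx) == 0) abort(sprintf("cell type '%s' has zero cells", ct))
    frac <- rowMeans(norm[, idx, drop = FALSE] >= min_value)
    keep <- keep | (frac >= min_frac)
  }
  rownames(norm)[keep]
}

#' Average normalized expression by cell type
#'
#' @param norm Normalized genes x cells matrix.
#' @param cell_type Cell-type label per column of `norm`.
#' @param tissue Tissue label stored with the result.
#'
#' @return An object of class `celltype_expr`: list with `tissue`, `values`
#'   (genes x cell types matrix of mean normalized expression, columns in
#'   lexicographic cell-type order) and `n_cells` (named integer).
#' @export
average_by_celltype <- function(norm, cell_type, tissue = "tissue") {
  if (length(cell_type) != ncol(norm)) {
    abort("`cell_type` must have one label per column of `norm`")
  }
  types <- sort(unique(as.character(cell_type)), method = "radix")
  values <- vapply(
    types,
    function(ct) rowMeans(norm[, cell_type == ct, drop = FALSE]),
    numeric(nrow(norm))
  )
  if (nrow(norm) == 1) values <- matrix(values, nrow = 1, dimnames = list(rownames(norm), types))
  n_cells <- vapply(types, function(ct) sum(cell_type == ct), integer(1))
  small <- n_cells < 10
  if (any(small)) {
    inform(sprintf(
      "%d cell type(s) with fewer than 10 cells: %s",
      sum(small), paste(types[small], collapse = ", ")
    ))
  }
  ord <- order(rownames(norm), method = "radix")
  structure(
    list(tissue = tissue, values = values[ord, , drop = FALSE], n_cells = n_cells),
    class = "celltype_expr"
  )
}

#' @export
print.celltype_expr <- function(x, ...) {
  cat(sprintf(
    "<celltype_expr> tissue '%s': %d genes x %d cell types\n",
    x$tissue, nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Retain genes exceeding the global median average expression
#'
#' Sparse single-cell profiles leave many genes near zero everywhere; only
#' genes whose average expression in some cell type strictly exceeds the
#' median over all entries of the average-expression matrix are retained for
#' preferential-expression scoring.
#'
#' @param avg A `celltype_expr` from [average_by_celltype()].
#'
#' @return Character vector of retained gene identifiers.
#' @export
retain_above_median <- function(avg) {
  stopifnot(inherits(avg, "celltype_expr"))
  if (length(avg$values) == 0) abort("empty average-expression matrix")
  med <- median(avg$values)
  keep <- apply(avg$values, 1, max) > med
  rownames(avg$values)[keep]
}

#' Preferential expression of genes across cell types
#'
#' For each gene, expression averages across the cell types of one tissue are
#' standardized to Z-scores: `P[g,c] = (e[g,c] - mean(e[g,])) / sd(e[g,])`.
#' A high value marks a gene preferentially expressed in that cell type.
#' Genes with zero cross-type variance carry no preference signal and are
#' dropped (reported via the `dropped_zero_sd` attribute).
#'
#' @param avg A `celltype_expr`, typically already subset to the genes kept
#'   by [retain_above_median()].
#' @param genes Optional character vector restricting the rows scored.
#' @param ddof Degrees-of-freedom convention for the SD: 0 (population,
#'   default) or 1 (sample).
#'
#' @return An object of class `pref_expr`: list with `tissue`, `z` (genes x
#'   cell types Z matrix), `ddof` and `dropped_zero_sd` (character vector).
#' @export
preferential_expression <- function(avg, genes = NULL, ddof = 0) {
  stopifnot(inherits(avg, "celltype_expr"))
  if (!ddof %in% c(0, 1)) abort("`ddof` must be 0 or 1")
  values <- avg$values
  if (!is.null(genes)) values <- values[rownames(values) %in% genes, , drop = FALSE]
  k <- ncol(values)
  if (k < 2) abort("preferential expression needs at least two cell types")
  mu <- rowMeans(values)
  centered <- values - mu
  denom <- if (ddof == 0) k else k - 1
  s <- sqrt(rowSums(centered^2) / denom)
  zero_sd <- s == 0
  z <- centered[!zero_sd, , drop = FALSE] / s[!zero_sd]
  structure(
    list(
      tissue = avg$tissue, z = z, ddof = ddof,
      dropped_zero_sd = rownames(values)[zero_sd]
    ),
    class = "pref_expr"
  )
}

#' @export
print.pref_expr <- function(x, ...) {
  cat(sprintf(
    "<pref_expr> tissue '%s': %d genes x %d cell types (ddof = %d)\n",
    x$tissue, nrow(x$z), ncol(x$z), x$ddof
  ))
  invisible(x)
}

#' @rdname preferential_expression
#' @param x A `pref_expr` object.
#' @param ... Unused.
#' @export
tidy.pref_expr <- function(x, ...) {
  as_tibble(x$z, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "cell_type", values_to = "z") |>
    mutate(tissue = x$tissue, .before = 1) |>
    arrange(.data$gene, .data$cell_type)
}

#' @rdname preferential_expression
#' @export
glance.pref_expr <- function(x, ...) {
  tibble(
    tissue = x$tissue, n_genes = nrow(x$z), n_cell_types = ncol(x$z),
    ddof = x$ddof, n_dropped_zero_sd = length(x$dropped_zero_sd)
  )
}

#' Run the per-tissue preferential-expression pipeline
#'
#' Applies, per tissue: cell-wise log-normalization, the expressed-gene
#' filter, cell-type averaging, the above-median retention rule and Z-score
#' standardization.
#'
#' @inheritParams normalize_counts
#' @inheritParams filter_expressed_genes
#' @inheritParams preferential_expression
#'
#' @return Named list of `pref_expr` objects, one per tissue (lexicographic
#'   tissue order).
#' @export
preferential_expression_by_tissue <- function(data, scale = 1e4,
                                              min_value = 0.05, min_frac = 0.10,
                                              ddof = 0, drop_zero_cells = FALSE) {
  stopifnot(inherits(data, "expr_dataset"))
  tissues <- sort(unique(data$cells$tissue), method = "radix")
  out <- lapply(tissues, function(ts) {
    idx <- data$cells$tissue == ts
    sub <- expression_dataset(
      data$counts[, idx, drop = FALSE],
      data$cells[idx, , drop = FALSE],
      species = data$species
    )
    norm <- normalize_counts(sub, scale = scale, drop_zero_cells = drop_zero_cells)
    cells <- attr(norm, "cells")
    expressed <- filter_expressed_genes(norm, cells$cell_type,
      min_value = min_value, min_frac = min_frac
    )
    avg <- average_by_celltype(norm[expressed, , drop = FALSE], cells$cell_type,
      tissue = ts
    )
    kept <- retain_above_median(avg)
    preferential_expression(avg, genes = kept, ddof = ddof)
  })
  names(out) <- tissues
  out
}
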
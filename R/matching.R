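#' Marker genes per cell type
#'
#' Markers of a cell type are genes with preferential-expression Z at or
#' above `threshold` (inclusive) in that cell type.
#'
#' @param z A `pref_expr` object or genes x cell-types Z matrix.
#' @param threshold Minimum Z (default 2).
#'
#' @return Tibble with columns `cell_type`, `gene`, sorted lexicographically.
#'   Cell types with no markers are absent (a message reports them).
#' @export
marker_genes <- function(z, threshold = 2) {
  zm <- if (inherits(z, "pref_expr")) z$z else z
  hits <- which(zm >= threshold, arr.ind = TRUE)
  out <- tibble(
    cell_type = colnames(zm)[hits[, "col"]],
    gene = rownames(zm)[hits[, "row"]]
  ) |>
    arrange(.data$cell_type, .data$gene)
  empty <- setdiff(colnames(zm), out$cell_type)
  if (length(empty) > 0) {
    inform(paste0("cell type(s) with no markers: ", paste(empty, collapse = ", ")))
  }
  out
}

#' Map marker genes through an ortholog table
#'
#' Each marker is replaced by the union of its orthologs in the target gene
#' space; markers with no ortholog are dropped and counted in the
#' `n_unmapped` attribute. Many-to-many maps are resolved by union.
#'
#' @param markers Tibble with columns `cell_type`, `gene` ([marker_genes()]).
#' @param ortholog_map Tibble with columns `from` and `to` gene identifiers
#'   (see `from`/`to` arguments).
#' @param from,to Column names of `ortholog_map` giving the source and
#'   target gene space (defaults `"gene_a"`, `"gene_b"`).
#'
#' @return Tibble with columns `cell_type`, `gene` in the target space,
#'   deduplicated; attribute `n_unmapped` counts dropped markers.
#' @export
map_orthologs <- function(markers, ortholog_map, from = "gene_a", to = "gene_b") {
  ortholog_map <- as_tibble(ortholog_map)
  if (nrow(ortholog_map) == 0) abort("empty ortholog map")
  if (!all(c(from, to) %in% names(ortholog_map))) {
    abort(sprintf("ortholog map must have columns '%s' and '%s'", from, to))
  }
  map_tbl <- ortholog_map |>
    select(gene = all_of(from), mapped = all_of(to)) |>
    distinct()
  n_unmapped <- markers |>
    anti_join(map_tbl, by = "gene") |>
    nrow()
  out <- markers |>
    inner_join(map_tbl, by = "gene", relationship = "many-to-many") |>
    distinct(.data$cell_type, gene = .data$mapped) |>
    arrange(.data$cell_type, .data$gene)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Jaccard index of two gene sets
#'
#' `|a intersect b| / |a union b|`; 0 when both sets are empty (an empty
#' overlap cannot support a match).
#'
#' @param a,b Character vectors (treated as sets).
#' @return A fraction in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Match cell types by marker-gene overlap
#'
#' Computes the Jaccard index for every pair of cell types across the two
#' marker tables (both in the same gene space; run [map_orthologs()] first
#' for cross-species comparisons). A pair is matched when its Jaccard index
#' reaches `jaccard_min` and lies in the top decile (inclusive) of all
#' pairwise values of the comparison.
#'
#' @param markers_a,markers_b Marker tibbles (`cell_type`, `gene`).
#' @param jaccard_min Minimum Jaccard index (default 0.05).
#' @param percentile_cut Quantile of the pooled pairwise Jaccard
#'   distribution a matching pair must reach, inclusive (default 0.90, i.e.
#'   the top 10th percentile).
#'
#' @return Tibble with columns `cell_type_a`, `cell_type_b`, `jaccard`,
#'   `percentile_rank` (fraction of pairwise values `<=` this one) and
#'   `matched`.
#' @export
call_matches <- function(markers_a, markers_b, jaccard_min = 0.05,
                         percentile_cut = 0.90) {
  sets_a <- split(markers_a$gene, markers_a$cell_type)
  sets_b <- split(markers_b$gene, markers_b$cell_type)
  if (length(sets_a) == 0 || length(sets_b) == 0) {
    abort("both marker tables must contain at least one cell type")
  }
  grid <- tidyr::expand_grid(
    cell_type_a = sort(names(sets_a), method = "radix"),
    cell_type_b = sort(names(sets_b), method = "radix")
  )
  jac <- map2_dbl_(grid$cell_type_a, grid$cell_type_b, function(a, b) {
    jaccard_index(sets_a[[a]], sets_b[[b]])
  })
  cutoff <- quantile(jac, percentile_cut, names = FALSE)
  grid |>
    mutate(
      jaccard = jac,
      percentile_rank = vapply(jac, function(v) mean(jac <= v), numeric(1)),
      matched = .data$jaccard >= jaccard_min & .data$jaccard >= cutoff
    )
}

map2_dbl_ <- function(x, y, f) {
  vapply(seq_along(x), function(i) f(x[i], y[i]), numeric(1))
}

#' Re-run matching after excluding genes from the marker lists
#'
#' Used to check that cell-type matching is not driven by a gene set of
#' interest (e.g. disease genes): the excluded genes are removed from both
#' marker tables, matching is recomputed, and concordance is the fraction of
#' originally matched pairs still matched.
#'
#' @inheritParams call_matches
#' @param exclude Character vector of genes to drop from both marker tables.
#'
#' @return List with `matches` (the re-run match table), `before` (the
#'   original), and `concordance` (fraction of original matches retained;
#'   `NaN` when nothing matched originally).
#' @export
rematch_excluding_genes <- function(markers_a, markers_b, exclude,
                                    jaccard_min = 0.05, percentile_cut = 0.90) {
  before <- call_matches(markers_a, markers_b, jaccard_min, percentile_cut)
  after <- call_matches(
    filter(markers_a, !.data$gene %in% exclude),
    filter(markers_b, !.data$gene %in% exclude),
    jaccard_min, percentile_cut
  )
  key <- function(m) paste(m$cell_type_a, m$cell_type_b, sep = "\r")
  matched_before <- key(before)[before$matched]
  matched_after <- key(after)[after$matched]
  concordance <- length(intersect(matched_before, matched_after)) /
    length(matched_before)
  list(matches = after, before = before, concordance = concordance)
}
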
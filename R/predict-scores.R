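#' Read or validate a disease catalog
#'
#' A disease catalog lists, per disease, its causal genes and affected
#' tissues, optionally with a per-gene function label (e.g. ligand,
#' receptor, oncogene, TSG).
#'
#' @param x A data frame with columns `disease_id`, `gene_id`, `tissue` and
#'   optionally `function_label`, or a path to a TSV with those columns.
#'
#' @return A tibble with the validated catalog.
#' @export
disease_catalog <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- readr::read_tsv(x, show_col_types = FALSE)
  }
  x <- as_tibble(x)
  required <- c("disease_id", "gene_id", "tissue")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("disease catalog is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(x[required]) > 0) {
    abort("(disease_id, gene_id, tissue) rows must be unique")
  }
  x
}

#' PrEDiCT score of a gene set per cell type
#'
#' The score of a disease in a cell type is the median preferential
#' expression of its genes there. Genes absent from the Z matrix are
#' dropped; `n_genes_used` records the effective set size.
#'
#' @param z A `pref_expr` object, or a genes x cell-types Z matrix.
#' @param genes Character vector of gene identifiers.
#'
#' @return Tibble with columns `cell_type`, `score`, `n_genes_used` and
#'   `note` (`NA` or `"no_expressed_genes"`). With an empty intersection all
#'   scores are `NA`.
#' @export
predict_score <- function(z, genes) {
  zm <- if (inherits(z, "pref_expr")) z$z else z
  used <- intersect(genes, rownames(zm))
  if (length(used) == 0) {
    return(tibble(
      cell_type = colnames(zm), score = NA_real_,
      n_genes_used = 0L, note = "no_expressed_genes"
    ))
  }
  scores <- apply(zm[used, , drop = FALSE], 2, median)
  tibble(
    cell_type = colnames(zm), score = unname(scores),
    n_genes_used = length(used), note = NA_character_
  )
}

# Random (or exhaustive) null score matrix: one gene set per row, scored in
# every cell type. Sampling uses the current RNG state.
null_score_matrix <- function(zm, n, reps, exhaustive = FALSE) {
  m <- nrow(zm)
  if (n > m) abort(sprintf("gene-set size %d exceeds universe of %d genes", n, m))
  if (exhaustive) {
    sets <- combn(m, n)
    reps <- ncol(sets)
    idx <- t(sets)
  } else {
    idx <- matrix(0L, nrow = reps, ncol = n)
    for (r in seq_len(reps)) idx[r, ] <- sample.int(m, n)
  }
  out <- matrix(NA_real_, nrow = reps, ncol = ncol(zm),
                dimnames = list(NULL, colnames(zm)))
  for (c_i in seq_len(ncol(zm))) {
    col <- zm[, c_i]
    vals <- matrix(col[t(idx)], nrow = n)
    out[, c_i] <- if (n == 1) vals[1, ] else apply(vals, 2, median)
  }
  out
}

#' Permutation p-values for PrEDiCT scores
#'
#' Under the null, a random gene set of the same size is drawn (without
#' replacement) from the expressed-gene universe of the tissue; each draw is
#' scored in every cell type, so the null preserves cross-cell-type
#' correlation. The p-value in a cell type is the fraction of random scores
#' at least as high as the observed score.
#'
#' @inheritParams predict_score
#' @param observed Tibble from [predict_score()] (columns `cell_type`,
#'   `score`), or a named numeric vector of observed scores.
#' @param n Gene-set size drawn per repeat.
#' @param reps Number of random gene sets (default 1000); ignored when
#'   `exhaustive = TRUE`.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (so a caller can seed once for a whole analysis).
#' @param exhaustive If `TRUE`, enumerate all `choose(m, n)` gene sets
#'   instead of sampling — exact, only sensible for small universes.
#' @param plus_one If `TRUE`, use the (k+1)/(reps+1) estimator instead of the
#'   plain fraction k/reps.
#'
#' @return Tibble with columns `cell_type`, `p_value`.
#' @export
permutation_pvalues <- function(z, observed, n, reps = 1000, seed = NULL,
                                exhaustive = FALSE, plus_one = FALSE) {
  zm <- if (inherits(z, "pref_expr")) z$z else z
  if (is.data.frame(observed)) {
    obs <- setNames(observed$score, observed$cell_type)
  } else {
    obs <- observed
  }
  obs <- obs[colnames(zm)]
  if (!is.null(seed)) set.seed(seed)
  null <- null_score_matrix(zm, n, reps, exhaustive = exhaustive)
  k <- colSums(sweep(null, 2, obs, ">="))
  p <- if (plus_one) (k + 1) / (nrow(null) + 1) else k / nrow(null)
  p[is.na(obs)] <- NA_real_
  tibble(cell_type = colnames(zm), p_value = unname(p))
}

#' Benjamini-Hochberg adjustment within groups
#'
#' @param p Numeric p-values.
#' @param group Grouping vector (e.g. disease x tissue); BH is applied
#'   within each group independently.
#'
#' @return Adjusted p-values in the input order.
#' @export
adjust_fdr <- function(p, group = rep(1L, length(p))) {
  if (length(p) != length(group)) abort("`p` and `group` lengths differ")
  out <- rep(NA_real_, length(p))
  for (g in unique(group)) {
    idx <- which(group == g)
    out[idx] <- p.adjust(p[idx], method = "BH")
  }
  out
}

#' Flag likely disease--cell-type associations
#'
#' An association is called likely when its score reaches the score
#' threshold (inclusive) and its FDR is below the FDR threshold (strict).
#'
#' @param result Tibble with columns `score` and `fdr`.
#' @param score_threshold Minimum PrEDiCT score (default 1, inclusive).
#' @param fdr_threshold FDR cutoff (default 0.1, strict `<`).
#'
#' @return `result` with a logical `likely` column (FALSE where score or fdr
#'   is `NA`).
#' @export
call_likely <- function(result, score_threshold = 1, fdr_threshold = 0.1) {
  result |>
    mutate(likely = !is.na(.data$score) & !is.na(.data$fdr) &
      .data$score >= score_threshold & .data$fdr < fdr_threshold)
}

#' Score all diseases of a catalog against their affected tissues
#'
#' For each disease and each of its affected tissues present in `pref`, the
#' disease's genes are scored in every cell type, a permutation null of the
#' same gene-set size yields per-cell-type p-values, p-values are BH-adjusted
#' within the disease x tissue group, and likely associations are flagged.
#'
#' @param pref A named list of `pref_expr` objects (names are tissues), or a
#'   single `pref_expr`.
#' @param catalog A [disease_catalog()] (tibble or TSV path).
#' @inheritParams permutation_pvalues
#' @inheritParams call_likely
#' @param seed Integer seed for the permutation null (default 1); set once
#'   at entry, diseases are processed in sorted order so results are
#'   reproducible.
#'
#' @return A tibble of class `predict_result` with columns `disease_id`,
#'   `tissue`, `cell_type`, `score`, `n_genes_used`, `n_genes_catalog`,
#'   `p_value`, `fdr`, `likely`, `note`. Attributes record `seed`, `reps`
#'   and the thresholds.
#' @export
predict_diseases <- function(pref, catalog, reps = 1000, seed = 1,
                             score_threshold = 1, fdr_threshold = 0.1,
                             exhaustive = FALSE, plus_one = FALSE) {
  if (inherits(pref, "pref_expr")) {
    pref <- setNames(list(pref), pref$tissue)
  }
  catalog <- disease_catalog(catalog)
  pairs <- catalog |>
    distinct(.data$disease_id, .data$tissue) |>
    filter(.data$tissue %in% names(pref)) |>
    arrange(.data$disease_id, .data$tissue)
  if (nrow(pairs) == 0) abort("no catalog tissue matches the preferential-expression tissues")
  set.seed(seed)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    d <- pairs$disease_id[i]
    ts <- pairs$tissue[i]
    z <- pref[[ts]]
    genes <- sort(unique(catalog$gene_id[catalog$disease_id == d & catalog$tissue == ts]),
                  method = "radix")
    obs <- predict_score(z, genes)
    n_used <- obs$n_genes_used[1]
    if (n_used > 0) {
      pv <- permutation_pvalues(z, obs, n = n_used, reps = reps,
                                exhaustive = exhaustive, plus_one = plus_one)
      obs <- left_join(obs, pv, by = "cell_type")
    } else {
      obs$p_value <- NA_real_
    }
    rows[[i]] <- obs |>
      mutate(disease_id = d, tissue = ts, n_genes_catalog = length(genes), .before = 1)
  }
  out <- list_rbind(rows) |>
    mutate(fdr = adjust_fdr(.data$p_value, paste(.data$disease_id, .data$tissue))) |>
    call_likely(score_threshold, fdr_threshold) |>
    select("disease_id", "tissue", "cell_type", "score", "n_genes_used",
           "n_genes_catalog", "p_value", "fdr", "likely", "note") |>
    arrange(.data$disease_id, .data$tissue, .data$cell_type)
  new_predict_result(out, seed = seed, reps = reps,
                     score_threshold = score_threshold,
                     fdr_threshold = fdr_threshold)
}

new_predict_result <- function(x, seed, reps, score_threshold, fdr_threshold) {
  structure(
    x,
    class = c("predict_result", class(tibble())),
    seed = seed, reps = reps,
    score_threshold = score_threshold, fdr_threshold = fdr_threshold
  )
}

#' @rdname predict_diseases
#' @param x A `predict_result`.
#' @param ... Unused.
#' @export
tidy.predict_result <- function(x, ...) {
  as_tibble(unclass2_tibble(x))
}

unclass2_tibble <- function(x) {
  class(x) <- class(tibble())
  attr(x, "seed") <- NULL
  attr(x, "reps") <- NULL
  attr(x, "score_threshold") <- NULL
  attr(x, "fdr_threshold") <- NULL
  x
}

#' @rdname predict_diseases
#' @export
glance.predict_result <- function(x, ...) {
  tibble(
    n_diseases = n_distinct(x$disease_id),
    n_associations = nrow(x),
    n_likely = sum(x$likely, na.rm = TRUE),
    reps = attr(x, "reps") %||% NA_integer_,
    seed = attr(x, "seed") %||% NA_integer_,
    score_threshold = attr(x, "score_threshold") %||% NA_real_,
    fdr_threshold = attr(x, "fdr_threshold") %||% NA_real_
  )
}

#' Score disease-gene subsets defined by function labels
#'
#' Re-runs the full scoring pipeline independently on each functional subset
#' of every disease's gene set (e.g. ligands vs receptors, oncogenes vs
#' TSGs), with the permutation null sized to the subset.
#'
#' @inheritParams predict_diseases
#' @param labels Optional character vector restricting which function labels
#'   are scored; unknown labels raise an error listing the valid ones.
#'
#' @return A `predict_result` tibble with an extra leading `subset` column.
#' @export
score_gene_subsets <- function(pref, catalog, labels = NULL, reps = 1000, seed = 1,
                               score_threshold = 1, fdr_threshold = 0.1,
                               exhaustive = FALSE, plus_one = FALSE) {
  catalog <- disease_catalog(catalog)
  if (!"function_label" %in% names(catalog)) {
    abort("catalog has no `function_label` column")
  }
  valid <- sort(unique(catalog$function_label[!is.na(catalog$function_label)]),
                method = "radix")
  labels <- labels %||% valid
  bad <- setdiff(labels, valid)
  if (length(bad) > 0) {
    abort(paste0(
      "unknown function label(s): ", paste(bad, collapse = ", "),
      "; valid labels: ", paste(valid, collapse = ", ")
    ))
  }
  out <- map(labels, function(lb) {
    sub <- filter(catalog, .data$function_label == lb)
    predict_diseases(pref, sub, reps = reps, seed = seed,
                     score_threshold = score_threshold,
                     fdr_threshold = fdr_threshold,
                     exhaustive = exhaustive, plus_one = plus_one) |>
      tidy() |>
      mutate(subset = lb, .before = 1)
  }) |> list_rbind()
  new_predict_result(out, seed = seed, reps = reps,
                     score_threshold = score_threshold,
                     fdr_threshold = fdr_threshold)
}
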
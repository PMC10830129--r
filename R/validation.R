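#' Literature co-appearance test for disease--cell-type pairs
#'
#' Given per-entity sets of literature record IDs, tests, per tissue,
#' whether each disease and cell type co-appear in more records than
#' expected. The universe is the union of all record IDs of that tissue's
#' entities; each pair forms a 2x2 table of record membership (both /
#' disease only / cell type only / neither) tested one-sided for
#' over-representation. Pairs with fewer than `min_joint` joint records are
#' excluded before testing, as are cell types never mentioned together with
#' any disease; p-values are Bonferroni-adjusted across the tissue's tested
#' pairs and a pair is supported when the adjusted p is below `alpha`.
#'
#' @param records Tibble with columns `entity_type` (`"disease"` or
#'   `"cell_type"`), `entity_id`, `tissue`, `record_id`.
#' @param min_joint Minimum joint record count for a pair to be tested
#'   (default 3).
#' @param alpha Significance cutoff on the Bonferroni-adjusted p (default
#'   0.001).
#' @param method `"fisher"` (one-sided exact, default) or `"chisq"`.
#' @param drop_disease If `TRUE`, a disease with any under-`min_joint` pair
#'   is dropped entirely (the stricter reading); default drops only the
#'   failing pairs.
#'
#' @return Tibble with one row per tested pair: `tissue`, `disease_id`,
#'   `cell_type`, the 2x2 counts (`joint`, `disease_only`, `celltype_only`,
#'   `neither`), `p_value`, `p_adj`, `supported`.
#' @export
coappearance_test <- function(records, min_joint = 3, alpha = 0.001,
                              method = c("fisher", "chisq"),
                              drop_disease = FALSE) {
  method <- match.arg(method)
  records <- as_tibble(records)
  required <- c("entity_type", "entity_id", "tissue", "record_id")
  if (!all(required %in% names(records))) {
    abort(paste0("`records` needs columns: ", paste(required, collapse = ", ")))
  }
  out <- list()
  for (ts in sort(unique(records$tissue), method = "radix")) {
    rt <- filter(records, .data$tissue == ts)
    universe <- unique(rt$record_id)
    if (length(universe) == 0) abort(sprintf("empty record universe for tissue '%s'", ts))
    dis <- filter(rt, .data$entity_type == "disease")
    cts <- filter(rt, .data$entity_type == "cell_type")
    d_sets <- split(dis$record_id, dis$entity_id)
    c_sets <- split(cts$record_id, cts$entity_id)
    if (length(d_sets) == 0 || length(c_sets) == 0) next
    pairs <- tidyr::expand_grid(
      disease_id = sort(names(d_sets), method = "radix"),
      cell_type = sort(names(c_sets), method = "radix")
    ) |>
      mutate(
        joint = map2_dbl_(.data$disease_id, .data$cell_type, function(d, c) {
          length(intersect(d_sets[[d]], c_sets[[c]]))
        })
      )
    # cell types never mentioned with any disease are excluded
    dead_ct <- pairs |>
      summarise(mx = max(.data$joint), .by = "cell_type") |>
      filter(.data$mx == 0) |>
      pull("cell_type")
    pairs <- filter(pairs, !.data$cell_type %in% dead_ct)
    if (drop_disease) {
      bad_d <- unique(pairs$disease_id[pairs$joint < min_joint])
      pairs <- filter(pairs, !.data$disease_id %in% bad_d)
    } else {
      pairs <- filter(pairs, .data$joint >= min_joint)
    }
    if (nrow(pairs) == 0) next
    n_u <- length(universe)
    pairs <- pairs |>
      mutate(
        disease_only = map_dbl(.data$disease_id, ~ length(unique(d_sets[[.x]]))) - .data$joint,
        celltype_only = map_dbl(.data$cell_type, ~ length(unique(c_sets[[.x]]))) - .data$joint,
        neither = n_u - .data$joint - .data$disease_only - .data$celltype_only,
        p_value = pmap_dbl_(
          .data$joint, .data$disease_only, .data$celltype_only, .data$neither,
          method
        ),
        p_adj = pmin(1, .data$p_value * dplyr::n()),
        supported = .data$p_adj < alpha,
        tissue = ts
      )
    out[[ts]] <- relocate(pairs, "tissue")
  }
  if (length(out) == 0) {
    return(tibble(
      tissue = character(), disease_id = character(), cell_type = character(),
      joint = double(), disease_only = double(), celltype_only = double(),
      neither = double(), p_value = double(), p_adj = double(),
      supported = logical()
    ))
  }
  list_rbind(unname(out))
}

pmap_dbl_ <- function(a, b, c, d, method) {
  vapply(seq_along(a), function(i) {
    tab <- matrix(c(a[i], b[i], c[i], d[i]), nrow = 2)
    if (method == "fisher") {
      fisher.test(tab, alternative = "greater")$p.value
    } else {
      suppressWarnings(chisq.test(tab)$p.value)
    }
  }, numeric(1))
}

#' Extract supported (gold) pairs from a co-appearance table
#'
#' @param coappearance Output of [coappearance_test()].
#' @return Tibble with columns `disease_id`, `tissue`, `cell_type`.
#' @export
gold_pairs <- function(coappearance) {
  coappearance |>
    filter(.data$supported) |>
    select("disease_id", "tissue", "cell_type")
}

#' Fisher enrichment of likely associations in a gold standard
#'
#' One-sided Fisher's exact test of the overlap between the likely set and
#' the gold set within a finite universe of evaluated associations.
#'
#' @param likely,gold Character vectors of association identifiers (any
#'   consistent encoding of disease--tissue--cell-type).
#' @param universe_size Total number of evaluated associations.
#'
#' @return Tibble with the 2x2 counts, `odds_ratio` and one-sided `p_value`.
#' @export
enrichment_fisher <- function(likely, gold, universe_size) {
  likely <- unique(likely)
  gold <- unique(gold)
  if (universe_size < length(union(likely, gold))) {
    abort("`universe_size` is smaller than the union of the two sets")
  }
  enrichment_fisher_counts(
    n_overlap = length(intersect(likely, gold)),
    n_likely = length(likely), n_gold = length(gold),
    n_universe = universe_size
  )
}

#' @rdname enrichment_fisher
#' @param n_overlap,n_likely,n_gold,n_universe The overlap count, the two
#'   set sizes and the universe size.
#' @export
enrichment_fisher_counts <- function(n_overlap, n_likely, n_gold, n_universe) {
  a <- n_overlap
  b <- n_likely - n_overlap
  c <- n_gold - n_overlap
  d <- n_universe - a - b - c
  if (min(a, b, c, d) < 0) abort("inconsistent counts")
  ft <- fisher.test(matrix(c(a, b, c, d), nrow = 2), alternative = "greater")
  tibble(
    overlap = a, likely_only = b, gold_only = c, neither = d,
    odds_ratio = unname(ft$estimate), p_value = ft$p.value
  )
}

#' False-positive and false-negative rates across FDR thresholds
#'
#' At each threshold `t`, the predicted set is every association with score
#' at or above the likely score cutoff and FDR below `t`. FPR is the
#' fraction of non-gold associations predicted; FNR is the fraction of gold
#' associations missed. FPR is non-decreasing and FNR non-increasing in `t`.
#'
#' @param result A `predict_result` tibble (or any tibble with `disease_id`,
#'   `tissue`, `cell_type`, `score`, `fdr`); its rows define the evaluated
#'   universe.
#' @param gold Tibble with columns `disease_id`, `tissue`, `cell_type`.
#' @param thresholds Numeric grid of FDR thresholds (default
#'   `seq(0, 1, by = 0.01)`).
#' @param score_threshold Score cutoff held fixed while the FDR threshold
#'   varies (default 1).
#'
#' @return Tibble with columns `threshold`, `n_predicted`, `fpr`, `fnr`.
#' @export
error_rates_vs_threshold <- function(result, gold,
                                     thresholds = seq(0, 1, by = 0.01),
                                     score_threshold = 1) {
  if (nrow(gold) == 0) abort("`gold` must be non-empty")
  key <- function(x) paste(x$disease_id, x$tissue, x$cell_type, sep = "\r")
  universe <- key(result)
  gold_k <- intersect(unique(key(gold)), universe)
  if (length(gold_k) == 0) abort("no gold pair lies in the evaluated universe")
  n_neg <- length(universe) - length(gold_k)
  eligible <- !is.na(result$score) & result$score >= score_threshold &
    !is.na(result$fdr)
  map(thresholds, function(t) {
    pred <- universe[eligible & result$fdr < t]
    tibble(
      threshold = t,
      n_predicted = length(pred),
      fpr = length(setdiff(pred, gold_k)) / n_neg,
      fnr = length(setdiff(gold_k, pred)) / length(gold_k)
    )
  }) |> list_rbind()
}

#' Correlation of PrEDiCT scores across matched cell types
#'
#' For every disease shared between two result tables (e.g. two species)
#' and every cell-type pair in the match table, the score in `cell_type_a`
#' is paired with the score in `cell_type_b`; Spearman correlation is
#' reported separately for matched and non-matched pairs.
#'
#' @param result_a,result_b `predict_result` tibbles for the two sides,
#'   scoring the same disease identifiers.
#' @param matches Match table from [call_matches()] (columns `cell_type_a`,
#'   `cell_type_b`, `matched`).
#'
#' @return Tibble with one row per stratum: `matched`, `n`, `spearman_r`
#'   (`NA` when fewer than 3 pairs).
#' @export
matched_score_correlation <- function(result_a, result_b, matches) {
  shared <- intersect(unique(result_a$disease_id), unique(result_b$disease_id))
  if (length(shared) == 0) abort("no shared diseases between the two result tables")
  a <- result_a |>
    filter(.data$disease_id %in% shared) |>
    select("disease_id", cell_type_a = "cell_type", score_a = "score")
  b <- result_b |>
    filter(.data$disease_id %in% shared) |>
    select("disease_id", cell_type_b = "cell_type", score_b = "score")
  paired <- matches |>
    select("cell_type_a", "cell_type_b", "matched") |>
    inner_join(a, by = "cell_type_a", relationship = "many-to-many") |>
    inner_join(b, by = c("cell_type_b", "disease_id")) |>
    filter(!is.na(.data$score_a) & !is.na(.data$score_b))
  paired |>
    summarise(
      n = dplyr::n(),
      spearman_r = if (dplyr::n() >= 3) {
        cor(.data$score_a, .data$score_b, method = "spearman")
      } else NA_real_,
      .by = "matched"
    ) |>
    arrange(.data$matched)
}

#' Permutation test for cross-tissue agreement of likely cell types
#'
#' For a reference tissue `Tr` and test tissue `Tt`, a disease is a success
#' when any of its likely cell types in `Tr` matches any of its likely cell
#' types in `Tt`. The observed success count `num_s` is compared to a null
#' in which, per disease, the `Tr` (or `Tt`) likely cell types are replaced
#' by a uniform draw of the same size from that tissue's cell types; the
#' p-value is the fraction of permutations whose success count reaches
#' `num_s`.
#'
#' @param result_r,result_t `predict_result` tibbles for the reference and
#'   test tissue (likely flags present). Each must cover a single tissue.
#' @param matches Match table whose `cell_type_a` lives in the reference
#'   tissue and `cell_type_b` in the test tissue.
#' @param reps Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param resample Which side is redrawn under the null: the reference
#'   tissue (default) or the test tissue.
#'
#' @return List with `num_s`, `n_diseases` (diseases evaluated),
#'   `n_skipped` (shared diseases lacking likely cell types on either
#'   side), `p_value` and `null` (integer success counts per permutation).
#' @export
matching_permutation_test <- function(result_r, result_t, matches,
                                      reps = 1000, seed = NULL,
                                      resample = c("reference", "test")) {
  resample <- match.arg(resample)
  if (!is.null(seed)) set.seed(seed)
  matched_pairs <- filter(matches, .data$matched)
  likely_sets <- function(res) {
    res <- filter(res, .data$likely)
    split(res$cell_type, res$disease_id)
  }
  lr <- likely_sets(result_r)
  lt <- likely_sets(result_t)
  shared <- intersect(unique(result_r$disease_id), unique(result_t$disease_id))
  eval_d <- sort(intersect(names(lr)[lengths(lr) > 0],
                           names(lt)[lengths(lt) > 0]), method = "radix")
  eval_d <- intersect(eval_d, shared)
  n_skipped <- length(shared) - length(eval_d)
  pair_key <- paste(matched_pairs$cell_type_a, matched_pairs$cell_type_b, sep = "\r")
  success <- function(set_r, set_t) {
    any(outer(set_r, set_t, paste, sep = "\r") %in% pair_key)
  }
  num_s <- sum(vapply(eval_d, function(d) success(lr[[d]], lt[[d]]), logical(1)))
  types_r <- sort(unique(result_r$cell_type), method = "radix")
  types_t <- sort(unique(result_t$cell_type), method = "radix")
  null <- vapply(seq_len(reps), function(i) {
    sum(vapply(eval_d, function(d) {
      if (resample == "reference") {
        rnd <- sample(types_r, length(lr[[d]]))
        success(rnd, lt[[d]])
      } else {
        rnd <- sample(types_t, length(lt[[d]]))
        success(lr[[d]], rnd)
      }
    }, logical(1)))
  }, integer(1))
  p <- if (length(eval_d) == 0) 1 else mean(null >= num_s)
  list(
    num_s = num_s, n_diseases = length(eval_d), n_skipped = n_skipped,
    p_value = p, null = null
  )
}
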
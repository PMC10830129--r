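make_records <- function(sets, tissue = "tis") {
  purrr::imap(sets, function(ids, e) {
    tibble::tibble(
      entity_type = if (startsWith(e, "d")) "disease" else "cell_type",
      entity_id = e, tissue = tissue, record_id = ids
    )
  }) |> purrr::list_rbind()
}

test_that("co-appearance p-values equal a hypergeometric tail oracle", {
  set.seed(33)
  universe <- sprintf("r%03d", 1:50)
  sets <- list(
    d1 = sample(universe, 20), d2 = sample(universe, 15),
    c1 = sample(universe, 18), c2 = sample(universe, 10)
  )
  res <- coappearance_test(make_records(sets), min_joint = 0, alpha = 0.001)
  for (i in seq_len(nrow(res))) {
    expect_equal(
      res$p_value[i],
      hyper_tail_oracle(res$joint[i], res$disease_only[i],
                        res$celltype_only[i], res$neither[i]),
      tolerance = 1e-12
    )
  }
  # Bonferroni across the tissue's tested pairs
  expect_equal(res$p_adj, pmin(1, res$p_value * nrow(res)))
})

test_that("identical record sets in a large universe are supported", {
  shared <- sprintf("r%03d", 1:10)
  filler <- sprintf("f%03d", 1:200)
  sets <- list(d1 = shared, c1 = shared, c2 = sample(filler, 30))
  res <- coappearance_test(make_records(sets))
  row <- res[res$disease_id == "d1" & res$cell_type == "c1", ]
  expect_true(row$supported)
})

test_that("pairs with fewer than three joint records are excluded before testing", {
  universe <- sprintf("r%03d", 1:100)
  sets <- list(
    d1 = universe[1:30],
    c1 = universe[29:60],   # joint = 2 with d1
    c2 = universe[1:10]     # joint = 10 with d1
  )
  res <- coappearance_test(make_records(sets))
  expect_false(any(res$disease_id == "d1" & res$cell_type == "c1"))
  expect_true(any(res$disease_id == "d1" & res$cell_type == "c2"))
  # the stricter reading drops the whole disease
  res2 <- coappearance_test(make_records(sets), drop_disease = TRUE)
  expect_equal(nrow(res2), 0)
})

test_that("cell types never mentioned with any disease are excluded", {
  universe <- sprintf("r%03d", 1:60)
  sets <- list(d1 = universe[1:20], c1 = universe[11:25], c2 = universe[41:60])
  res <- coappearance_test(make_records(sets), min_joint = 3)
  expect_false("c2" %in% res$cell_type)
})

test_that("enrichment test reproduces exact tail probabilities", {
  # small table vs the explicit tail-sum oracle
  got <- enrichment_fisher_counts(5, 10, 10, 100)
  expect_equal(got$p_value, hyper_tail_oracle(5, 5, 5, 85), tolerance = 1e-12)
  # set-based interface agrees with the count-based one
  likely <- sprintf("p%02d", 1:10)
  gold <- sprintf("p%02d", 6:15)
  via_sets <- enrichment_fisher(likely, gold, 100)
  expect_equal(via_sets$p_value, got$p_value)
  expect_error(enrichment_fisher(likely, gold, 12), "universe_size")
  # likely = gold gives the minimal p over overlaps at fixed margins
  best <- enrichment_fisher(likely, likely, 100)
  worse <- enrichment_fisher(likely, c(likely[1:9], "other"), 100)
  expect_lt(best$p_value, worse$p_value)
})

test_that("error-rate curves equal brute-force set arithmetic and are monotone", {
  set.seed(52)
  result <- tibble::tibble(
    disease_id = rep(sprintf("d%d", 1:4), each = 5),
    tissue = "tis",
    cell_type = rep(sprintf("c%d", 1:5), 4),
    score = runif(20, 0, 3),
    fdr = runif(20)
  )
  gold <- result[sample(20, 6), c("disease_id", "tissue", "cell_type")]
  thr <- seq(0, 1, by = 0.05)
  curve <- error_rates_vs_threshold(result, gold, thresholds = thr)
  # oracle at a few thresholds
  key <- function(x) paste(x$disease_id, x$tissue, x$cell_type)
  gk <- key(gold)
  for (t in c(0, 0.25, 0.6, 1)) {
    i <- which.min(abs(curve$threshold - t))
    pred <- key(result)[result$score >= 1 & result$fdr < t]
    expect_equal(curve$fpr[i], length(setdiff(pred, gk)) / (20 - length(gk)))
    expect_equal(curve$fnr[i], length(setdiff(gk, pred)) / length(gk))
  }
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$fnr) <= 0))
  # boundary thresholds
  expect_equal(curve$fpr[curve$threshold == 0], 0)
  expect_equal(curve$fnr[curve$threshold == 0], 1)
  expect_error(error_rates_vs_threshold(result, gold[0, ]), "non-empty")
})

test_that("matched-score correlation strata behave as expected", {
  types <- sprintf("ct%d", 1:4)
  diseases <- sprintf("d%02d", 1:30)
  set.seed(8)
  base <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(diseases, types))
  mk_result <- function(scores) {
    tibble::tibble(
      disease_id = rep(diseases, each = 4), tissue = "tis",
      cell_type = rep(types, 30),
      score = as.vector(t(scores))
    )
  }
  matches <- tidyr::expand_grid(cell_type_a = types, cell_type_b = types) |>
    dplyr::mutate(matched = cell_type_a == cell_type_b)
  # identical scores across species -> r = 1 in the matched stratum
  r_same <- matched_score_correlation(mk_result(base), mk_result(base), matches)
  expect_equal(r_same$spearman_r[r_same$matched], 1)
  # independently shuffled scores -> |r| small in both strata
  shuffled <- base[sample(30), sample(4)]
  dimnames(shuffled) <- dimnames(base)
  r_null <- matched_score_correlation(mk_result(base), mk_result(shuffled), matches)
  expect_true(all(abs(r_null$spearman_r) < 0.2))
  expect_true(all(r_null$n >= 3))
})

test_that("tie-heavy score vectors reproduce a midrank oracle", {
  a_scores <- c(1, 1, 2, 2, 3, 3, 3, 4)
  b_scores <- c(2, 2, 2, 1, 4, 4, 3, 3)
  diseases <- sprintf("d%d", 1:8)
  mk <- function(s) tibble::tibble(disease_id = diseases, tissue = "tis",
                                   cell_type = "ct1", score = s)
  matches <- tibble::tibble(cell_type_a = "ct1", cell_type_b = "ct1", matched = TRUE)
  got <- matched_score_correlation(mk(a_scores), mk(b_scores), matches)
  # oracle: Pearson correlation of midranks computed by hand
  midrank <- function(x) {
    sapply(x, function(v) sum(x < v) + (1 + sum(x == v)) / 2)
  }
  ra <- midrank(a_scores); rb <- midrank(b_scores)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(got$spearman_r, oracle, tolerance = 1e-12)
})

test_that("matching permutation test agrees with exact enumeration", {
  types_r <- sprintf("r%d", 1:4)
  types_t <- sprintf("t%d", 1:4)
  mk_res <- function(types, likely_by_d) {
    purrr::imap(likely_by_d, function(lk, d) {
      tibble::tibble(disease_id = d, tissue = "x", cell_type = types,
                     likely = types %in% lk)
    }) |> purrr::list_rbind()
  }
  res_r <- mk_res(types_r, list(d1 = "r1", d2 = c("r2", "r3"), d3 = "r4"))
  res_t <- mk_res(types_t, list(d1 = "t1", d2 = "t2", d3 = "t3"))
  matches <- tibble::tibble(
    cell_type_a = c("r1", "r2", "r4"),
    cell_type_b = c("t1", "t3", "t3"),
    matched = TRUE
  )
  out <- matching_permutation_test(res_r, res_t, matches, reps = 20000, seed = 3)
  # success: d1 (r1-t1), d2 (no: matched partners of r2,r3 are t3, likely_t = t2), d3 (r4-t3)
  expect_equal(out$num_s, 2)
  expect_equal(out$n_diseases, 3)
  # exact null via per-disease success probabilities over all C(4, k) draws
  succ_prob <- function(k, likely_t) {
    sets <- combn(types_r, k, simplify = FALSE)
    mean(sapply(sets, function(s) {
      any(paste(rep(s, each = length(likely_t)), likely_t) %in%
            paste(matches$cell_type_a, matches$cell_type_b))
    }))
  }
  q <- c(succ_prob(1, "t1"), succ_prob(2, "t2"), succ_prob(1, "t3"))
  # P(num_r >= 2) by direct convolution of three Bernoullis
  p_exact <- q[1] * q[2] * q[3] +
    q[1] * q[2] * (1 - q[3]) + q[1] * (1 - q[2]) * q[3] + (1 - q[1]) * q[2] * q[3]
  expect_lt(abs(out$p_value - p_exact), 0.01)
})

test_that("matching permutation degenerate cases hit the definitional bounds", {
  types <- sprintf("c%d", 1:3)
  res <- tibble::tibble(disease_id = rep(c("d1", "d2"), each = 3),
                        tissue = "x", cell_type = rep(types, 2),
                        likely = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  # no matched pairs at all -> num_s = 0, p = 1
  empty <- tibble::tibble(cell_type_a = character(), cell_type_b = character(),
                          matched = logical())
  out0 <- matching_permutation_test(res, res, empty, reps = 50, seed = 1)
  expect_equal(out0$num_s, 0)
  expect_equal(out0$p_value, 1)
  # every pair matched -> saturated null, p = 1
  full <- tidyr::expand_grid(cell_type_a = types, cell_type_b = types) |>
    dplyr::mutate(matched = TRUE)
  out1 <- matching_permutation_test(res, res, full, reps = 50, seed = 1)
  expect_equal(out1$num_s, out1$n_diseases)
  expect_equal(out1$p_value, 1)
  # reproducible under a fixed seed
  a <- matching_permutation_test(res, res, full, reps = 100, seed = 9)
  b <- matching_permutation_test(res, res, full, reps = 100, seed = 9)
  expect_identical(a, b)
})
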
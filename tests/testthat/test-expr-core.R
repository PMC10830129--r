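test_that("normalization matches the log1p library-size formula", {
  counts <- matrix(c(10, 90), nrow = 2,
                   dimnames = list(c("gA", "gB"), "c1"))
  norm <- normalize_counts(counts, scale = 1e4)
  expect_equal(norm[, 1], c(gA = log(1 + 1000), gB = log(1 + 9000)))

  # zero counts stay zero whatever the cell total
  counts2 <- matrix(c(0, 5, 0, 17), nrow = 2,
                    dimnames = list(c("gA", "gB"), c("c1", "c2")))
  norm2 <- normalize_counts(counts2)
  expect_equal(unname(norm2[1, ]), c(0, 0))

  # monotone in count within a cell
  expect_true(norm[2, 1] > norm[1, 1])
})

test_that("zero-total cells error by name or are dropped under the flag", {
  counts <- matrix(c(1, 2, 0, 0), nrow = 2,
                   dimnames = list(c("gA", "gB"), c("ok", "empty")))
  expect_error(normalize_counts(counts), "empty")
  expect_message(normalize_counts(counts, drop_zero_cells = TRUE), "dropping 1")
  dropped <- suppressMessages(normalize_counts(counts, drop_zero_cells = TRUE))
  expect_equal(colnames(dropped), "ok")
})

test_that("expressed-gene filter equals an exhaustive per-type check", {
  toy <- toy_counts(genes = 20, types = 3, n_per_type = 6, seed = 3)
  norm <- normalize_counts(toy$counts)
  got <- filter_expressed_genes(norm, toy$cell_type)
  want <- character()
  for (g in rownames(norm)) {
    ok <- FALSE
    for (ct in unique(toy$cell_type)) {
      cells <- which(toy$cell_type == ct)
      if (mean(norm[g, cells] >= 0.05) >= 0.10) ok <- TRUE
    }
    if (ok) want <- c(want, g)
  }
  expect_identical(got, want)

  # a gene at zero everywhere is excluded
  norm0 <- rbind(norm, gZ = 0)
  expect_false("gZ" %in% filter_expressed_genes(norm0, toy$cell_type))
})

test_that("filter boundary is inclusive: >= min_value in exactly min_frac of cells", {
  # 10 cells of one type, exactly 1 (10%) at exactly 0.05
  norm <- matrix(0, nrow = 1, ncol = 10,
                 dimnames = list("g1", sprintf("c%d", 1:10)))
  norm[1, 1] <- 0.05
  expect_identical(filter_expressed_genes(norm, rep("t1", 10)), "g1")
  # just below either bound -> excluded
  norm[1, 1] <- 0.0499
  expect_length(filter_expressed_genes(norm, rep("t1", 10)), 0)
})

test_that("filter is monotone in min_value and min_frac", {
  toy <- toy_counts(genes = 30, types = 4, n_per_type = 8, seed = 9)
  norm <- normalize_counts(toy$counts)
  base <- filter_expressed_genes(norm, toy$cell_type, 0.05, 0.10)
  for (mv in c(0.1, 0.5, 1)) {
    expect_true(all(
      filter_expressed_genes(norm, toy$cell_type, mv, 0.10) %in% base
    ))
  }
  for (mf in c(0.2, 0.5, 0.9)) {
    expect_true(all(
      filter_expressed_genes(norm, toy$cell_type, 0.05, mf) %in% base
    ))
  }
})

test_that("cell-type averages equal brute-force group means", {
  toy <- toy_counts(genes = 20, types = 5, n_per_type = 4, seed = 21)
  norm <- normalize_counts(toy$counts)
  avg <- suppressMessages(average_by_celltype(norm, toy$cell_type, tissue = "x"))
  for (ct in unique(toy$cell_type)) {
    for (g in rownames(norm)) {
      expect_equal(avg$values[g, ct], mean(norm[g, toy$cell_type == ct]))
    }
  }
  expect_equal(unname(avg$n_cells), rep(4L, 5))
})

test_that("above-median retention uses a strict inequality over all entries", {
  # constant matrix: nothing strictly exceeds the median
  flat <- structure(
    list(tissue = "x",
         values = matrix(1, 4, 3, dimnames = list(paste0("g", 1:4), paste0("t", 1:3))),
         n_cells = c(t1 = 2L, t2 = 2L, t3 = 2L)),
    class = "celltype_expr"
  )
  expect_length(retain_above_median(flat), 0)

  # one dominant gene is retained
  dom <- flat
  dom$values["g2", "t3"] <- 50
  expect_identical(retain_above_median(dom), "g2")

  # random toy equals the brute-force rule
  toy <- toy_counts(genes = 10, types = 4, n_per_type = 5, seed = 2)
  norm <- normalize_counts(toy$counts)
  avg <- suppressMessages(average_by_celltype(norm, toy$cell_type))
  got <- retain_above_median(avg)
  med <- median(as.vector(avg$values))
  want <- rownames(avg$values)[apply(avg$values, 1, function(x) max(x) > med)]
  expect_identical(got, want)
})

test_that("preferential expression matches the hand-computed Z example", {
  vals <- matrix(c(2, 0, 0, 0), nrow = 1,
                 dimnames = list("g1", paste0("t", 1:4)))
  avg <- structure(list(tissue = "x", values = rbind(vals, g2 = c(1, 2, 3, 4)),
                        n_cells = setNames(rep(2L, 4), paste0("t", 1:4))),
                   class = "celltype_expr")
  pe <- preferential_expression(avg, ddof = 0)
  expect_equal(unname(pe$z["g1", ]),
               c(sqrt(3), -1 / sqrt(3), -1 / sqrt(3), -1 / sqrt(3)),
               tolerance = 1e-12)
})

test_that("constant genes are dropped and rows are centered with unit SD", {
  avg <- structure(
    list(tissue = "x",
         values = rbind(
           gflat = c(3, 3, 3, 3),
           gvar = c(1, 5, 2, 0),
           gvar2 = c(0, 0, 1, 7)
         ),
         n_cells = setNames(rep(2L, 4), paste0("t", 1:4))),
    class = "celltype_expr"
  )
  colnames(avg$values) <- paste0("t", 1:4)
  pe <- preferential_expression(avg, ddof = 0)
  expect_identical(pe$dropped_zero_sd, "gflat")
  expect_equal(unname(rowMeans(pe$z)), rep(0, 2), tolerance = 1e-10)
  sds <- apply(pe$z, 1, function(x) sqrt(sum((x - mean(x))^2) / length(x)))
  expect_equal(unname(sds), rep(1, 2), tolerance = 1e-10)

  # sample-SD convention also standardizes under its own ddof
  pe1 <- preferential_expression(avg, ddof = 1)
  sds1 <- apply(pe1$z, 1, sd)
  expect_equal(unname(sds1), rep(1, 2), tolerance = 1e-10)
})

test_that("a single-cell-type tissue cannot be standardized", {
  avg <- structure(
    list(tissue = "x",
         values = matrix(1:3, 3, 1, dimnames = list(paste0("g", 1:3), "t1")),
         n_cells = c(t1 = 5L)),
    class = "celltype_expr"
  )
  expect_error(preferential_expression(avg), "two cell types")
})

test_that("cell-type relabeling permutes the pipeline output identically", {
  toy <- toy_counts(genes = 25, types = 4, n_per_type = 6, seed = 7)
  norm <- normalize_counts(toy$counts)
  avg1 <- suppressMessages(average_by_celltype(norm, toy$cell_type))
  # swap labels of types t1 and t4
  relab <- c(t1 = "t4", t2 = "t2", t3 = "t3", t4 = "t1")[toy$cell_type]
  avg2 <- suppressMessages(average_by_celltype(norm, relab))
  expect_equal(unname(avg1$values[, c("t1", "t2", "t3", "t4")]),
               unname(avg2$values[, c("t4", "t2", "t3", "t1")]))
  pe1 <- preferential_expression(avg1, genes = retain_above_median(avg1))
  pe2 <- preferential_expression(avg2, genes = retain_above_median(avg2))
  expect_equal(pe1$z[, "t1"], pe2$z[, "t4"])
})

test_that("the per-tissue pipeline equals a naive double-loop oracle", {
  data <- toy_dataset(genes = 40, types = 6, n_per_type = 5, seed = 13)
  pref <- suppressMessages(preferential_expression_by_tissue(data))[["toyT"]]

  # oracle: recompute everything with explicit loops
  counts <- as.matrix(data$counts)
  norm <- counts
  for (j in seq_len(ncol(counts))) {
    norm[, j] <- log1p(counts[, j] * 1e4 / sum(counts[, j]))
  }
  ct <- data$cells$cell_type
  types <- sort(unique(ct))
  expressed <- rownames(norm)[sapply(rownames(norm), function(g) {
    any(sapply(types, function(t) mean(norm[g, ct == t] >= 0.05) >= 0.10))
  })]
  avg <- sapply(types, function(t) rowMeans(norm[expressed, ct == t, drop = FALSE]))
  med <- median(as.vector(avg))
  kept <- rownames(avg)[apply(avg, 1, max) > med]
  z_oracle <- t(apply(avg[kept, , drop = FALSE], 1, function(x) {
    (x - mean(x)) / sqrt(sum((x - mean(x))^2) / length(x))
  }))
  expect_equal(pref$z, z_oracle[rownames(pref$z), , drop = FALSE], tolerance = 1e-12)
  expect_setequal(rownames(pref$z), kept)
})
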
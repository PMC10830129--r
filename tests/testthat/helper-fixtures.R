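# Small deterministic fixtures shared across test files.

# A toy raw count matrix: `genes` x (`n_per_type` cells per cell type).
toy_counts <- function(genes = 10, types = 3, n_per_type = 5, seed = 11,
                       lambda_max = 6) {
  set.seed(seed)
  n_cells <- types * n_per_type
  counts <- matrix(
    rpois(genes * n_cells, lambda = runif(genes, 0, lambda_max)),
    nrow = genes,
    dimnames = list(
      sprintf("g%02d", seq_len(genes)),
      sprintf("c%02d", seq_len(n_cells))
    )
  )
  # guarantee no zero-total cell
  counts[1, ] <- counts[1, ] + 1L
  list(
    counts = counts,
    cell_type = rep(sprintf("t%d", seq_len(types)), each = n_per_type)
  )
}

toy_dataset <- function(genes = 12, types = 3, n_per_type = 5, seed = 11) {
  toy <- toy_counts(genes, types, n_per_type, seed)
  cells <- tibble::tibble(
    cell_id = colnames(toy$counts),
    tissue = "toyT",
    cell_type = toy$cell_type,
    sample = "s1"
  )
  expression_dataset(toy$counts, cells, species = "toy")
}

# A toy preferential-expression object built from explicit Z values.
toy_pref <- function(z, tissue = "toyT") {
  structure(
    list(tissue = tissue, z = z, ddof = 0, dropped_zero_sd = character()),
    class = "pref_expr"
  )
}

# Z matrix with named genes/cell types filled from a seeded normal draw.
random_z <- function(genes = 8, types = 4, seed = 5) {
  set.seed(seed)
  vals <- matrix(rnorm(genes * types), nrow = genes,
                 dimnames = list(sprintf("g%02d", seq_len(genes)),
                                 sprintf("ct%d", seq_len(types))))
  # row-standardize (population convention) so it is a genuine Z matrix
  mu <- rowMeans(vals)
  s <- sqrt(rowSums((vals - mu)^2) / types)
  (vals - mu) / s
}

# One-sided hypergeometric tail by explicit probability summation --
# independent of fisher.test / phyper.
hyper_tail_oracle <- function(a, b, c, d) {
  m <- a + b        # size of set 1
  k <- a + c        # size of set 2
  n <- a + b + c + d
  amax <- min(m, k)
  tail <- 0
  for (x in a:amax) {
    tail <- tail + exp(
      lchoose(m, x) + lchoose(n - m, k - x) - lchoose(n, k)
    )
  }
  tail
}

# Exhaustive PrEDiCT permutation p-values by direct enumeration over all
# gene subsets of size n (loop oracle, no shared code with the package).
enumeration_oracle <- function(z, obs, n) {
  sets <- combn(nrow(z), n)
  p <- numeric(ncol(z))
  for (ci in seq_len(ncol(z))) {
    scores <- apply(sets, 2, function(s) median(z[s, ci]))
    p[ci] <- mean(scores >= obs[ci])
  }
  p
}
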
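#' Simulation configuration
#'
#' Parameters for the synthetic two-pseudo-species generator. Counts are
#' negative binomial (overdispersed, UMI-like); each cell type carries a
#' planted set of marker genes elevated `marker_fold`-fold, and each disease
#' a planted affected cell type in which its genes are elevated to a target
#' preferential-expression Z of `effect_z`.
#'
#' With `K` cell types per tissue, the preferential-expression Z of a gene
#' elevated in a single type is bounded by `sqrt(K - 1)`; `effect_z` must
#' stay below that bound (hence the default of 12 cell types for a target
#' of 3).
#'
#' @param seed Integer seed driving the whole generation.
#' @param tissues Number of tissues.
#' @param cell_types_per_tissue Cell types per tissue.
#' @param cells_per_type Cells per cell type.
#' @param genes Number of genes.
#' @param markers_per_type Planted marker genes per cell type.
#' @param marker_fold Multiplicative count-mean elevation of markers in
#'   their own cell type.
#' @param diseases Number of diseases (assigned to tissues round-robin).
#' @param genes_per_disease Integer range `c(min, max)` of genes per disease.
#' @param effect_z Target preferential-expression Z of planted disease
#'   genes in their affected cell type; 0 plants no effect.
#' @param base_mean Baseline negative-binomial mean per gene per cell
#'   (scaled by a lognormal per-gene factor).
#' @param dispersion Negative-binomial size parameter.
#' @param ortholog_noise Fraction of ortholog-map entries scrambled when
#'   generating a species pair (must be < 0.5).
#' @param subset_effects If `TRUE`, each disease's genes are split into
#'   ligand/receptor halves planted in two different cell types (for
#'   function-subset analyses); by default all of a disease's genes share
#'   one affected cell type and labels are still assigned.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, tissues = 2, cell_types_per_tissue = 12,
                       cells_per_type = 40, genes = 1500,
                       markers_per_type = 25, marker_fold = 8,
                       diseases = 20, genes_per_disease = c(3, 10),
                       effect_z = 3, base_mean = 0.3, dispersion = 2,
                       ortholog_noise = 0, subset_effects = FALSE) {
  cfg <- list(
    seed = seed, tissues = tissues,
    cell_types_per_tissue = cell_types_per_tissue,
    cells_per_type = cells_per_type, genes = genes,
    markers_per_type = markers_per_type, marker_fold = marker_fold,
    diseases = diseases, genes_per_disease = genes_per_disease,
    effect_z = effect_z, base_mean = base_mean, dispersion = dispersion,
    ortholog_noise = ortholog_noise, subset_effects = subset_effects
  )
  counts <- c("tissues", "cell_types_per_tissue", "cells_per_type", "genes",
              "markers_per_type", "diseases")
  for (nm in counts) {
    if (cfg[[nm]] < 1) abort(sprintf("`%s` must be a positive count", nm))
  }
  if (cfg$markers_per_type * cfg$cell_types_per_tissue +
        max(cfg$genes_per_disease) > cfg$genes) {
    abort("not enough genes for the requested markers and disease genes")
  }
  if (cfg$effect_z < 0) abort("`effect_z` must be non-negative")
  k <- cfg$cell_types_per_tissue
  if (cfg$effect_z > 0 && cfg$effect_z^2 >= k - 1) {
    abort(sprintf(
      "effect_z = %g is unattainable with %d cell types (bound sqrt(%d)); increase cell_types_per_tissue",
      cfg$effect_z, k, k - 1
    ))
  }
  if (cfg$ortholog_noise < 0 || cfg$ortholog_noise >= 0.5) {
    abort("`ortholog_noise` must be in [0, 0.5)")
  }
  if (cfg$base_mean <= 0 || cfg$dispersion <= 0) {
    abort("`base_mean` and `dispersion` must be positive")
  }
  structure(cfg, class = "sim_config")
}

# Planted design shared by both pseudo-species: marker sets per cell type,
# disease catalog with affected cell types, function labels.
sim_structure <- function(cfg) {
  gene_ids <- sprintf("g%05d", seq_len(cfg$genes))
  tissues <- sprintf("tissue%02d", seq_len(cfg$tissues))
  types <- sprintf("ct%02d", seq_len(cfg$cell_types_per_tissue))
  markers <- list()
  disease_pool <- list()
  for (ts in tissues) {
    picked <- sample(gene_ids, cfg$markers_per_type * cfg$cell_types_per_tissue)
    markers[[ts]] <- tibble(
      tissue = ts,
      cell_type = rep(types, each = cfg$markers_per_type),
      gene = picked
    )
    disease_pool[[ts]] <- setdiff(gene_ids, picked)
  }
  markers <- list_rbind(unname(markers))
  disease_ids <- sprintf("disease%03d", seq_len(cfg$diseases))
  catalog <- list()
  planted <- list()
  for (i in seq_len(cfg$diseases)) {
    d <- disease_ids[i]
    ts <- tissues[((i - 1) %% cfg$tissues) + 1]
    sizes <- seq(cfg$genes_per_disease[1], cfg$genes_per_disease[2])
    n_genes <- sizes[sample.int(length(sizes), 1)]
    genes_d <- sample(disease_pool[[ts]], n_genes)
    labels <- rep(c("ligand", "receptor"), length.out = n_genes)
    if (cfg$subset_effects && cfg$cell_types_per_tissue >= 2) {
      cts <- sample(types, 2)
      affected <- cts[(labels != "ligand") + 1]
      planted[[d]] <- tibble(
        disease_id = d, tissue = ts, cell_type = cts, subset = c("ligand", "receptor")
      )
    } else {
      ct <- sample(types, 1)
      affected <- rep(ct, n_genes)
      planted[[d]] <- tibble(
        disease_id = d, tissue = ts, cell_type = ct, subset = NA_character_
      )
    }
    catalog[[d]] <- tibble(
      disease_id = d, gene_id = genes_d, tissue = ts,
      function_label = labels, affected_cell_type = affected
    )
  }
  list(
    gene_ids = gene_ids, tissues = tissues, cell_types = types,
    markers = markers, catalog = list_rbind(unname(catalog)),
    planted = list_rbind(unname(planted)),
    # lognormal per-gene baseline; meanlog/sdlog chosen so the expressed-gene
    # filter retains roughly half the genes at the default base_mean
    lambda = setNames(stats::rlnorm(cfg$genes, meanlog = -2, sdlog = 1.2), gene_ids)
  )
}

# Expected normalized value E[log1p(c * factor)] for c ~ NB(mu, size).
nb_lognorm_mean <- function(mu, size, factor) {
  if (mu <= 0) return(0)
  cmax <- max(10, stats::qnbinom(1 - 1e-10, size = size, mu = mu))
  cc <- 0:cmax
  sum(stats::dnbinom(cc, size = size, mu = mu) * log1p(cc * factor))
}

# Invert nb_lognorm_mean in mu (monotone increasing).
nb_mu_for_target <- function(target, size, factor, upper = 1e4) {
  if (target <= 0) return(0)
  f <- function(mu) nb_lognorm_mean(mu, size, factor) - target
  if (f(upper) < 0) return(upper)
  stats::uniroot(f, c(1e-8, upper), tol = 1e-6)$root
}

# Draw one tissue's baseline count matrix (markers planted, diseases not).
sim_tissue_counts <- function(cfg, st, ts, gene_ids) {
  k <- cfg$cell_types_per_tissue
  n_cells <- k * cfg$cells_per_type
  mk <- filter(st$markers, .data$tissue == ts)
  counts <- matrix(0L, nrow = cfg$genes, ncol = n_cells,
                   dimnames = list(gene_ids, NULL))
  mu_base <- cfg$base_mean * st$lambda[gene_ids]
  for (j in seq_len(k)) {
    ct <- st$cell_types[j]
    mu <- mu_base
    mg <- mk$gene[mk$cell_type == ct]
    mu[mg] <- mu[mg] * cfg$marker_fold
    cols <- ((j - 1) * cfg$cells_per_type + 1):(j * cfg$cells_per_type)
    counts[, cols] <- rnbinom(cfg$genes * cfg$cells_per_type,
                              size = cfg$dispersion, mu = mu)
  }
  counts
}

# Elevate disease genes in their affected cell type to hit the target Z.
# The required shift on the normalized-mean scale follows from inverting
# z = d (K-1)/K / sqrt(s^2 + d^2 (K-1)/K^2) at the tissue's estimated
# cross-type noise SD s, then mapping back to a count mean numerically.
plant_disease_effects <- function(counts, cfg, st, ts, cell_type_of_col) {
  if (cfg$effect_z == 0) return(counts)
  cat_ts <- filter(st$catalog, .data$tissue == ts)
  if (nrow(cat_ts) == 0) return(counts)
  k <- cfg$cell_types_per_tissue
  norm <- log1p(sweep(counts, 2, Matrix::colSums(counts) / 1e4, "/"))
  avg <- vapply(st$cell_types,
                function(ct) rowMeans(norm[, cell_type_of_col == ct, drop = FALSE]),
                numeric(nrow(norm)))
  s_g <- apply(avg, 1, function(x) sqrt(sum((x - mean(x))^2) / k))
  s <- median(s_g[rowMeans(avg) > 0.05])
  z <- cfg$effect_z
  d <- z * s * k / sqrt((k - 1) * (k - 1 - z^2))
  t_bar <- mean(colSums(counts))
  factor <- 1e4 / t_bar
  for (i in seq_len(nrow(cat_ts))) {
    g <- cat_ts$gene_id[i]
    ct <- cat_ts$affected_cell_type[i]
    target <- mean(avg[g, st$cell_types != ct]) + d
    mu <- nb_mu_for_target(target, cfg$dispersion, factor)
    cols <- which(cell_type_of_col == ct)
    counts[g, cols] <- rnbinom(length(cols), size = cfg$dispersion, mu = mu)
  }
  counts
}

sim_species_dataset <- function(cfg, st, species, gene_prefix) {
  gene_ids <- paste0(gene_prefix, st$gene_ids)
  all_counts <- list()
  all_cells <- list()
  for (ts in st$tissues) {
    cell_type_of_col <- rep(st$cell_types, each = cfg$cells_per_type)
    counts <- sim_tissue_counts(cfg, st, ts, st$gene_ids)
    counts <- plant_disease_effects(counts, cfg, st, ts, cell_type_of_col)
    rownames(counts) <- gene_ids
    ids <- sprintf("%s_%s_c%04d", species, ts, seq_len(ncol(counts)))
    colnames(counts) <- ids
    all_counts[[ts]] <- counts
    all_cells[[ts]] <- tibble(
      cell_id = ids, tissue = ts, cell_type = cell_type_of_col,
      sample = sprintf("%s_s%d", ts, rep(1:2, length.out = ncol(counts)))
    )
  }
  expression_dataset(
    do.call(cbind, unname(all_counts)),
    list_rbind(unname(all_cells)),
    species = species
  )
}

sim_truth <- function(st, cfg, gene_prefix_a = "", gene_prefix_b = NULL) {
  truth <- list(
    planted = st$planted,
    catalog = st$catalog |>
      mutate(gene_id = paste0(gene_prefix_a, .data$gene_id)) |>
      select("disease_id", "gene_id", "tissue", "function_label"),
    markers = mutate(st$markers, gene = paste0(gene_prefix_a, .data$gene)),
    cell_types = tidyr::expand_grid(tissue = st$tissues, cell_type = st$cell_types),
    config = cfg
  )
  structure(truth, class = "sim_truth")
}

#' Generate a synthetic single-species dataset with planted ground truth
#'
#' Draws negative-binomial counts for every tissue, elevates each cell
#' type's planted markers `marker_fold`-fold, and elevates each disease's
#' genes in its planted affected cell type to a target
#' preferential-expression Z of `effect_z` (self-calibrated against the
#' dataset's own cross-type noise). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param species Species label.
#'
#' @return List with `dataset` (an [expression_dataset()]) and `truth`
#'   (class `sim_truth`: `planted` triples, the disease `catalog`, planted
#'   `markers`, the `cell_types` table and the config).
#' @export
generate_dataset <- function(config, species = "speciesA") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  st <- sim_structure(config)
  dataset <- sim_species_dataset(config, st, species, gene_prefix = "")
  list(dataset = dataset, truth = sim_truth(st, config))
}

#' Generate a synthetic species pair with an ortholog map
#'
#' Both pseudo-species share the planted design (markers, diseases,
#' affected cell types) but re-draw counts independently; species B uses
#' its own gene identifiers linked to species A by a one-to-one ortholog
#' map, of which an `ortholog_noise` fraction is scrambled.
#'
#' @inheritParams generate_dataset
#'
#' @return List with `dataset_a`, `dataset_b`, `ortholog_map` (tibble
#'   `gene_a`, `gene_b`), `truth_a`, `truth_b` (per-species gene spaces;
#'   planted triples are shared).
#' @export
generate_species_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  st <- sim_structure(config)
  dataset_a <- sim_species_dataset(config, st, "speciesA", gene_prefix = "")
  dataset_b <- sim_species_dataset(config, st, "speciesB", gene_prefix = "m.")
  map <- tibble(gene_a = st$gene_ids, gene_b = paste0("m.", st$gene_ids))
  n_noise <- floor(config$ortholog_noise * nrow(map))
  if (n_noise >= 2) {
    idx <- sample(nrow(map), n_noise)
    map$gene_b[idx] <- map$gene_b[c(idx[-1], idx[1])]
  }
  truth_b <- sim_truth(st, config, gene_prefix_a = "m.")
  truth_b$markers <- mutate(st$markers, gene = paste0("m.", .data$gene))
  list(
    dataset_a = dataset_a, dataset_b = dataset_b, ortholog_map = map,
    truth_a = sim_truth(st, config), truth_b = truth_b
  )
}

#' Generate synthetic literature record sets and gold pairs
#'
#' Emulates PubMed-style record sets: every disease and cell type of each
#' planted tissue owns a random set of record IDs; records of planted
#' disease--cell-type pairs are additionally co-assigned to both entities
#' with probability `base_rate^2 * (signal - 1)`, so `signal = 1` yields
#' independent (null) sets and larger values make planted pairs co-appear.
#'
#' @param truth A `sim_truth` from [generate_dataset()].
#' @param n_records Records per tissue universe (default 2000).
#' @param signal Odds multiplier for planted-pair co-appearance
#'   (default 20; must be >= 1).
#' @param base_rate Baseline record-membership probability (default 0.05).
#' @param seed Integer seed.
#'
#' @return List with `records` (tibble `entity_type`, `entity_id`,
#'   `tissue`, `record_id`) and `gold` (the planted triples).
#' @export
generate_literature <- function(truth, n_records = 2000, signal = 20,
                                base_rate = 0.05, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (signal < 1) abort("`signal` must be >= 1")
  set.seed(seed)
  q <- min(0.9, base_rate^2 * (signal - 1))
  rows <- list()
  for (ts in sort(unique(truth$cell_types$tissue), method = "radix")) {
    rec_ids <- sprintf("%s_r%05d", ts, seq_len(n_records))
    diseases <- sort(unique(truth$catalog$disease_id[truth$catalog$tissue == ts]),
                     method = "radix")
    types <- sort(truth$cell_types$cell_type[truth$cell_types$tissue == ts],
                  method = "radix")
    member <- list()
    for (e in c(diseases, types)) {
      member[[e]] <- runif(n_records) < base_rate
    }
    planted_ts <- filter(truth$planted, .data$tissue == ts)
    for (i in seq_len(nrow(planted_ts))) {
      joint <- runif(n_records) < q
      d <- planted_ts$disease_id[i]
      ct <- planted_ts$cell_type[i]
      member[[d]] <- member[[d]] | joint
      member[[ct]] <- member[[ct]] | joint
    }
    for (e in names(member)) {
      if (!any(member[[e]])) next
      rows[[paste(ts, e)]] <- tibble(
        entity_type = if (e %in% diseases) "disease" else "cell_type",
        entity_id = e, tissue = ts, record_id = rec_ids[member[[e]]]
      )
    }
  }
  list(
    records = list_rbind(unname(rows)),
    gold = select(truth$planted, "disease_id", "tissue", "cell_type")
  )
}
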
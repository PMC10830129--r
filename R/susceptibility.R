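#' Cell-type susceptibility to disease
#'
#' The susceptibility of a cell type is the fraction of its tissue's
#' diseases that likely affect it.
#'
#' @param result A `predict_result` tibble with `likely` flags; its rows
#'   define which diseases were evaluated in each tissue.
#'
#' @return Tibble with columns `tissue`, `cell_type`, `n_likely_diseases`,
#'   `n_tissue_diseases`, `susceptibility`.
#' @export
susceptibility <- function(result) {
  per_tissue <- result |>
    summarise(n_tissue_diseases = n_distinct(.data$disease_id), .by = "tissue")
  result |>
    summarise(
      n_likely_diseases = n_distinct(.data$disease_id[.data$likely]),
      .by = c("tissue", "cell_type")
    ) |>
    left_join(per_tissue, by = "tissue") |>
    mutate(susceptibility = ifelse(.data$n_tissue_diseases == 0, NA_real_,
      .data$n_likely_diseases / .data$n_tissue_diseases
    )) |>
    arrange(.data$tissue, .data$cell_type)
}

#' Cell-type prevalence within tissues
#'
#' The fraction of a tissue's cells belonging to each cell type; sums to 1
#' per tissue.
#'
#' @param data An [expression_dataset()], or a cell annotation tibble with
#'   columns `tissue` and `cell_type`.
#'
#' @return Tibble with columns `tissue`, `cell_type`, `n_cells`,
#'   `prevalence`.
#' @export
prevalence <- function(data) {
  cells <- if (inherits(data, "expr_dataset")) data$cells else as_tibble(data)
  cells |>
    count(.data$tissue, .data$cell_type, name = "n_cells") |>
    mutate(prevalence = .data$n_cells / sum(.data$n_cells), .by = "tissue") |>
    arrange(.data$tissue, .data$cell_type)
}

#' Identify prevalent cell classes
#'
#' A class is prevalent when it spans more than `min_types` cell types
#' across at least `min_tissues` tissues.
#'
#' @param susc Susceptibility tibble ([susceptibility()]).
#' @param classes Tibble mapping `cell_type` to `class`.
#' @param min_types,min_tissues Prevalence criteria (defaults 15 and 4).
#'
#' @return Character vector of prevalent class labels.
#' @export
prevalent_classes <- function(susc, classes, min_types = 15, min_tissues = 4) {
  susc |>
    inner_join(classes, by = "cell_type") |>
    summarise(
      n_types = n_distinct(paste(.data$tissue, .data$cell_type)),
      n_tissues = n_distinct(.data$tissue),
      .by = "class"
    ) |>
    filter(.data$n_types > min_types, .data$n_tissues >= min_tissues) |>
    pull("class")
}

#' Compare susceptibility across cell classes
#'
#' Runs a one-way ANOVA of susceptibility across cell classes, a two-sided
#' Mann-Whitney U test of each prevalent class against all other cell types
#' (BH-adjusted across classes), and, when prevalence is supplied, the
#' Pearson correlation of susceptibility with prevalence over cell types.
#'
#' @inheritParams prevalent_classes
#' @param prevalence Optional prevalence tibble ([prevalence()]), joined on
#'   `tissue` and `cell_type`.
#' @param prevalent Optional character vector of class labels to test with
#'   Mann-Whitney; defaults to [prevalent_classes()] computed from the
#'   input.
#'
#' @return An object of class `class_tests`: list with `anova` (tibble:
#'   `f_statistic`, `p_value`, `df_between`, `df_within`), `mwu` (tibble per
#'   tested class: `class`, `n_in`, `n_out`, `median_in`, `median_out`,
#'   `p_value`, `p_adj`), and `pearson` (tibble: `r`, `p_value`, `n`, or
#'   `NULL` without prevalence).
#' @export
class_tests <- function(susc, classes, prevalence = NULL, prevalent = NULL,
                        min_types = 15, min_tissues = 4) {
  df <- susc |>
    inner_join(classes, by = "cell_type") |>
    filter(!is.na(.data$susceptibility))
  if (nrow(df) == 0) abort("no cell type with both susceptibility and a class")
  n_per <- count(df, .data$class)
  anova_tbl <- if (stats::var(df$susceptibility) == 0) {
    # constant response: no between-class variance, by convention F = 0
    tibble(
      f_statistic = 0, p_value = 1,
      df_between = n_distinct(df$class) - 1L,
      df_within = nrow(df) - n_distinct(df$class)
    )
  } else if (sum(n_per$n >= 2) >= 2 && n_distinct(df$class) >= 2) {
    fit <- aov(susceptibility ~ class, data = df)
    sm <- summary(fit)[[1]]
    tibble(
      f_statistic = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1],
      df_between = sm[["Df"]][1], df_within = sm[["Df"]][2]
    )
  } else {
    tibble(
      f_statistic = NA_real_, p_value = NA_real_,
      df_between = NA_integer_, df_within = NA_integer_
    )
  }
  prevalent <- prevalent %||% prevalent_classes(susc, classes, min_types, min_tissues)
  mwu <- map(sort(prevalent, method = "radix"), function(cl) {
    x <- df$susceptibility[df$class == cl]
    y <- df$susceptibility[df$class != cl]
    p <- if (length(x) >= 1 && length(y) >= 1) {
      suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
    } else NA_real_
    # fully tied samples: the normal approximation degenerates, no evidence
    if (is.nan(p)) p <- 1
    tibble(
      class = cl, n_in = length(x), n_out = length(y),
      median_in = median(x), median_out = median(y), p_value = p
    )
  }) |> list_rbind()
  if (nrow(mwu) > 0) mwu$p_adj <- p.adjust(mwu$p_value, method = "BH")
  pearson <- NULL
  if (!is.null(prevalence)) {
    joined <- inner_join(susc, prevalence, by = c("tissue", "cell_type")) |>
      filter(!is.na(.data$susceptibility))
    if (nrow(joined) >= 3) {
      ct <- cor.test(joined$susceptibility, joined$prevalence, method = "pearson")
      pearson <- tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(joined))
    } else {
      pearson <- tibble(r = NA_real_, p_value = NA_real_, n = nrow(joined))
    }
  }
  structure(list(anova = anova_tbl, mwu = mwu, pearson = pearson),
            class = "class_tests")
}

#' @export
print.class_tests <- function(x, ...) {
  cat("<class_tests>\n  ANOVA: F =", signif(x$anova$f_statistic, 4),
      ", p =", signif(x$anova$p_value, 4), "\n")
  if (nrow(x$mwu) > 0) {
    cat("  Mann-Whitney (BH-adjusted) per prevalent class:\n")
    print(x$mwu)
  }
  if (!is.null(x$pearson)) {
    cat("  Pearson r(susceptibility, prevalence) =", signif(x$pearson$r, 4), "\n")
  }
  invisible(x)
}

#' @rdname class_tests
#' @param x A `class_tests` object.
#' @param ... Unused.
#' @export
tidy.class_tests <- function(x, ...) {
  x$mwu
}

#' @rdname class_tests
#' @export
glance.class_tests <- function(x, ...) {
  tibble(
    anova_f = x$anova$f_statistic, anova_p = x$anova$p_value,
    n_classes_tested = nrow(x$mwu),
    pearson_r = if (!is.null(x$pearson)) x$pearson$r else NA_real_,
    pearson_p = if (!is.null(x$pearson)) x$pearson$p_value else NA_real_
  )
}
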
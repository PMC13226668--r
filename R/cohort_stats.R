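#' Attribute similarity between glycemic states
#'
#' Cosine similarity `S(a, b) = sum a_i b_i / (||a|| ||b||)` of two
#' z-dimensional attribute vectors (z = 4 by convention: fraction female,
#' fraction of the majority ancestry, min-max scaled mean age and mean BMI).
#'
#' @param a,b non-zero numeric vectors of equal length.
#' @return similarity in `[-1, 1]`.
#' @export
state_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero attribute vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Encode per-state attribute vectors from donor metadata
#'
#' @param donors donor tibble with `state`, `sex`, `ancestry`, `age`, `bmi`.
#' @return matrix states x 4 (`frac_female`, `frac_majority_ancestry`,
#'   `age_scaled`, `bmi_scaled`), age/BMI min-max scaled over states.
#' @export
state_attribute_vectors <- function(donors) {
  major <- names(sort(table(donors$ancestry), decreasing = TRUE))[1]
  byst <- donors |>
    dplyr::group_by(state) |>
    dplyr::summarise(frac_female = mean(sex == "F"),
                     frac_majority_ancestry = mean(ancestry == major),
                     age = mean(age), bmi = mean(bmi), .groups = "drop")
  mm <- function(x) if (diff(range(x)) == 0) rep(0.5, length(x)) else
    (x - min(x)) / diff(range(x))
  m <- cbind(frac_female = byst$frac_female,
             frac_majority_ancestry = byst$frac_majority_ancestry,
             age_scaled = mm(byst$age), bmi_scaled = mm(byst$bmi))
  rownames(m) <- as.character(byst$state)
  m
}

#' Per-donor cell type composition
#'
#' Percentages per donor under two denominator conventions: `overall` (all
#' kept cells) and `endocrine` (beta/alpha/delta/gamma only; epsilon cells
#' are rare and excluded by default).
#'
#' @param cells kept-cell tibble with `donor_id`, `cell_type`.
#' @param donors donor tibble (for `state`).
#' @param endocrine_types the endocrine denominator.
#' @return tibble `donor_id`, `state`, `cell_type`, `pct_overall`,
#'   `pct_endocrine` (NA outside the endocrine set).
#' @export
composition_table <- function(cells, donors,
                              endocrine_types = c("beta", "alpha", "delta",
                                                  "gamma")) {
  tab <- cells |>
    dplyr::filter(!is.na(cell_type), !is.na(donor_id)) |>
    dplyr::count(donor_id, cell_type) |>
    dplyr::group_by(donor_id) |>
    dplyr::mutate(pct_overall = 100 * n / sum(n),
                  pct_endocrine = dplyr::if_else(
                    cell_type %in% endocrine_types,
                    100 * n / sum(n[cell_type %in% endocrine_types]),
                    NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::left_join(donors |> dplyr::select(donor_id, state, hba1c),
                     by = "donor_id")
  tab
}

#' ANOVA plus Tukey HSD composition comparison across states
#'
#' Per cell type, one-way ANOVA of per-donor percentages across glycemic
#' states with Tukey HSD pairwise comparisons (studentized-range p);
#' Bonferroni correction across cell types.
#'
#' @param ct output of [composition_table()].
#' @param value `"pct_endocrine"` (default) or `"pct_overall"`.
#' @param alpha significance level after correction.
#' @return list `anova` and `pairs` tibbles.
#' @export
composition_tests <- function(ct, value = "pct_endocrine", alpha = 0.05) {
  ct$y <- ct[[value]]
  ct <- ct |> dplyr::filter(!is.na(y))
  types <- unique(ct$cell_type)
  n_types <- length(types)
  res_a <- list(); res_p <- list()
  for (ty in types) {
    d <- ct[ct$cell_type == ty, ]
    counts <- table(droplevels(factor(d$state)))
    if (length(counts) < 2 || any(counts < 2)) {
      warning("cell type ", ty, " skipped (absent or single-donor state)")
      next
    }
    fit <- stats::aov(y ~ state, data = d)
    s <- summary(fit)[[1]]
    res_a[[ty]] <- tibble::tibble(cell_type = ty, F = s$`F value`[1],
                                  p = s$`Pr(>F)`[1])
    res_p[[ty]] <- .tukey_pairs(d$y, d$state) |>
      dplyr::mutate(cell_type = ty, .before = 1)
  }
  pairs <- dplyr::bind_rows(res_p) |>
    dplyr::mutate(p_bonf = pmin(1, p * n_types),
                  significant = p_bonf <= alpha,
                  direction = ifelse(diff > 0, "higher", "lower"))
  list(anova = dplyr::bind_rows(res_a), pairs = pairs)
}

#' Spearman correlation between composition and a donor trait
#'
#' @param ct output of [composition_table()].
#' @param trait donor-level trait column present in `ct` (default `hba1c`).
#' @param value composition column (default `pct_endocrine`).
#' @return tibble `cell_type`, `rho`, `p`.
#' @export
composition_trait_correlation <- function(ct, trait = "hba1c",
                                          value = "pct_endocrine") {
  ct$y <- ct[[value]]; ct$tr <- ct[[trait]]
  ct |>
    dplyr::filter(!is.na(y)) |>
    dplyr::group_by(cell_type) |>
    dplyr::summarise({
      if (dplyr::n_distinct(tr) < 2) {
        tibble::tibble(rho = NA_real_, p = NA_real_)
      } else {
        cc <- suppressWarnings(stats::cor.test(y, tr, method = "spearman"))
        tibble::tibble(rho = unname(cc$estimate), p = cc$p.value)
      }
    }, .groups = "drop")
}

#' Games-Howell pairwise post-hoc test
#'
#' Welch-type pairwise comparisons that do not assume equal variances:
#' for each pair, `t = (m_i - m_j) / sqrt(s_i^2/n_i + s_j^2/n_j)` with
#' Welch-Satterthwaite degrees of freedom, referred to the studentized range
#' as `q = t * sqrt(2)` with the full number of groups.
#'
#' @param values numeric observations.
#' @param groups group labels (each group needs >= 3 values).
#' @return tibble `group1`, `group2`, `diff`, `df`, `p`.
#' @export
games_howell <- function(values, groups) {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  n <- tapply(values, groups, length)
  if (any(n < 3)) stop("each group needs at least 3 values", call. = FALSE)
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  pairs <- utils::combn(levels(groups), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se2 <- v[a] / n[a] + v[b] / n[b]
    t <- (m[b] - m[a]) / sqrt(se2)
    df <- se2^2 / ((v[a] / n[a])^2 / (n[a] - 1) +
                     (v[b] / n[b])^2 / (n[b] - 1))
    tibble::tibble(group1 = a, group2 = b, diff = unname(m[b] - m[a]),
                   df = unname(df),
                   p = unname(stats::ptukey(abs(t) * sqrt(2), k, df,
                                            lower.tail = FALSE)))
  })
}

#' Composition-vs-trait scatter plot
#' @param ct output of [composition_table()].
#' @param cell_type cell type to display.
#' @param value,trait columns plotted.
#' @return a ggplot.
#' @export
plot_composition_trait <- function(ct, cell_type = "beta",
                                   value = "pct_endocrine",
                                   trait = "hba1c") {
  d <- ct[ct$cell_type == cell_type & !is.na(ct[[value]]), ]
  ggplot2::ggplot(d, ggplot2::aes(.data[[value]], .data[[trait]],
                                  colour = state)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", se = TRUE, level = 0.99,
                         colour = "grey40", formula = y ~ x) +
    ggplot2::labs(x = paste(cell_type, "percentage"), y = trait) +
    ggplot2::theme_minimal()
}
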
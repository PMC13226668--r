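#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjustment of the Rand index; 1 for identical partitions
#' (up to label names), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(length(a))
  max_ind <- (sum_a + sum_b) / 2
  if (max_ind == expected) return(1)
  (sum_ij - expected) / (max_ind - expected)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidier methods for isletpipe fitted objects
#'
#' `tidy()` returns one row per (gene, model term) for an NB-GLM fit;
#' `glance()` a one-row model summary.
#'
#' @param x a fitted object.
#' @param ... unused.
#' @name tidy-isletpipe
NULL

#' @keywords internal
"_PACKAGE"

utils::globalVariables(c(
  ".data", "A", "F", "M", "OR", "a", "age", "aligned_allele", "b",
  "barcode_id", "best_type", "bin", "bmi", "call", "candidate", "cell_type",
  "class", "cluster", "concordant", "deg_log2fc", "diff", "direction",
  "donor_id", "enriched", "fdr", "filtered", "flag_quantile",
  "flag_threshold", "frac", "gene", "gene_id", "group", "hba1c", "hit",
  "ko_dir", "level", "library_id", "locus_id", "log2fc", "module", "n",
  "n_flags", "n_signals", "odds_ratio", "orientation_known", "other_allele",
  "p", "p_bonf", "pMT", "pct_endocrine", "pct_overall", "prot_p",
  "prot_sign", "q", "quantile", "r2", "reason", "rho", "risk_allele",
  "sample_id", "score", "sex", "shrunk", "state", "tr", "trait", "variant_id",
  "y", "z", "empty", "oriented_z", "effect_allele", "cohort_directions",
  "ancestry", "doublet"))
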
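#' Cluster-level doublet enrichment test
#'
#' For each cluster the 2x2 table of (doublets, singlets) x (in, out) is
#' tested with a two-sided Fisher exact test; the odds ratio
#' `OR = DR_in / DR_out` of the in/out doublet ratios gets a Haldane-Anscombe
#' 0.5 correction when any table cell is zero (the exact p is unaffected).
#' FDR is Benjamini-Hochberg across clusters, and a cluster is called
#' enriched when `OR > 2` and `FDR <= 1%`.
#'
#' @param labels per-cell cluster labels (or an `snn_clustering`).
#' @param doublet_flags logical per-cell consensus doublet flags.
#' @param or_min,fdr_max enrichment thresholds (defaults 2 and 0.01).
#' @return tibble with one row per cluster: counts, `DR_in`, `DR_out`, `OR`,
#'   `p`, `fdr`, `enriched`.
#' @export
doublet_enrichment_test <- function(labels, doublet_flags, or_min = 2,
                                    fdr_max = 0.01) {
  if (inherits(labels, "snn_clustering")) labels <- labels$labels
  stopifnot(length(labels) == length(doublet_flags))
  cls <- sort(unique(labels))
  if (length(cls) < 2)
    stop("doublet enrichment needs at least 2 clusters", call. = FALSE)
  res <- purrr::map_dfr(cls, function(cl) {
    d_in <- sum(doublet_flags & labels == cl)
    s_in <- sum(!doublet_flags & labels == cl)
    d_out <- sum(doublet_flags & labels != cl)
    s_out <- sum(!doublet_flags & labels != cl)
    tab <- matrix(c(d_in, s_in, d_out, s_out), 2)
    p <- stats::fisher.test(tab)$p.value
    hc <- if (any(tab == 0)) 0.5 else 0
    or <- ((d_in + hc) / (s_in + hc)) / ((d_out + hc) / (s_out + hc))
    tibble::tibble(cluster = cl, d_in = d_in, s_in = s_in, d_out = d_out,
                   s_out = s_out,
                   DR_in = d_in / s_in, DR_out = d_out / s_out,
                   OR = or, p = p)
  })
  res |>
    dplyr::mutate(fdr = stats::p.adjust(p, "BH"),
                  enriched = OR > or_min & fdr <= fdr_max)
}

#' Multi-hormone co-expression flags per cluster
#'
#' Flags clusters whose cluster-mean z-scores exceed `z_min` for two or more
#' hormone genes - the expression corroboration used before removing a
#' doublet-enriched cluster.
#'
#' @param nm normalized genes-by-cells matrix.
#' @param labels per-cell cluster labels.
#' @param hormones hormone gene ids.
#' @param z_min z-score threshold (default 1).
#' @return tibble `cluster`, `n_hormones_high`, `coexpression_flag`.
#' @export
hormone_coexpression_flags <- function(nm, labels,
                                       hormones = c("INS", "GCG", "SST",
                                                    "PPY", "GHRL"),
                                       z_min = 1) {
  if (inherits(labels, "snn_clustering")) labels <- labels$labels
  horm <- intersect(hormones, rownames(nm))
  cls <- sort(unique(labels))
  means <- vapply(cls, function(cl)
    rowMeans(nm[horm, labels == cl, drop = FALSE]), numeric(length(horm)))
  means <- matrix(means, nrow = length(horm),
                  dimnames = list(horm, cls))
  z <- t(scale(t(means)))
  z[is.nan(z)] <- 0
  tibble::tibble(cluster = cls,
                 n_hormones_high = colSums(z > z_min),
                 coexpression_flag = colSums(z > z_min) >= 2)
}

#' Remove doublet-enriched clusters and residual scored doublets
#'
#' Clusters are removed when statistically enriched and (with
#' `require_both = TRUE`, the default) also multi-hormone flagged; their
#' member cells get reason `enriched_doublet_cluster`. All remaining
#' consensus-scored doublets are removed with reason `consensus_doublet`.
#'
#' @param cells cell tibble with `barcode_id`, `filtered`, `reason`.
#' @param labels per-cell cluster labels aligned to `cells`.
#' @param enrichment output of [doublet_enrichment_test()].
#' @param coexpr output of [hormone_coexpression_flags()].
#' @param doublet_flags logical consensus doublet flags aligned to `cells`.
#' @param require_both require hormone corroboration for cluster removal.
#' @return `cells` with updated `filtered`/`reason`.
#' @export
remove_enriched_clusters <- function(cells, labels, enrichment, coexpr,
                                     doublet_flags, require_both = TRUE) {
  if (inherits(labels, "snn_clustering")) labels <- labels$labels
  enr <- dplyr::left_join(enrichment, coexpr, by = "cluster")
  kill <- enr$cluster[enr$enriched &
                        (!require_both | enr$coexpression_flag)]
  spared <- enr$cluster[enr$enriched & require_both &
                          !enr$coexpression_flag]
  if (length(spared))
    warning("enriched but single-hormone cluster(s) retained: ",
            paste(spared, collapse = ", "))
  in_kill <- labels %in% kill
  add_reason <- function(reason, hit) dplyr::case_when(
    hit & is.na(cells$reason) ~ reason,
    hit ~ paste(cells$reason, reason, sep = ","),
    TRUE ~ cells$reason)
  cells$reason <- add_reason("enriched_doublet_cluster", in_kill)
  cells$filtered <- dplyr::coalesce(cells$filtered, FALSE) | in_kill
  resid <- doublet_flags & !in_kill
  cells$reason <- add_reason("consensus_doublet", resid)
  cells$filtered <- cells$filtered | resid
  cells
}
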
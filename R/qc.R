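#' Quality-control threshold set
#'
#' Bundles every QC cutoff. Defaults: preliminary filter drops droplets with
#' `nFEA <= 500`, `nUMI <= 1000` or `pMT >= 50%`; the per-library feature
#' cutoff is `nFEA < 1400`, relaxed to `1000` when the flagged cells enrich an
#' exocrine cluster; `pMT > 40%` at the library stage; beta cells are later
#' excluded at `pMT >= 40%` and all other types at `>= 20%`. Doublet
#' simulation uses `pN = 0.25` artificial doublets, neighborhood fraction
#' `pK = 0.09`, expected doublet fraction `nExp = 0.1`, `nPC = 10` components
#' and score threshold `0.25`.
#'
#' @param ... overrides of any default named below.
#' @return named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(...) {
  th <- list(prelim_nfea = 500, prelim_numi = 1000, prelim_pmt = 50,
             nfea_default = 1400, nfea_relaxed = 1000, pmt_cut = 40,
             celltype_pmt = c(beta = 40, other = 20),
             exocrine_enrich_frac = 0.5,
             pN = 0.25, pK = 0.09, nExp = 0.1, nPC = 10,
             sim_threshold = 0.25)
  over <- list(...)
  stopifnot(all(names(over) %in% names(th)))
  th[names(over)] <- over
  structure(th, class = "qc_thresholds")
}

#' Per-droplet QC metrics
#'
#' `nUMI` = total UMIs (column sum), `nFEA` = genes detected, `pMT` = percent
#' of UMIs mapped to mitochondrial genes. Droplets with zero totals get
#' `pMT = 0` with a warning.
#'
#' @param m a [counts_matrix()].
#' @param mito_gene_set character vector of mitochondrial gene ids (non-empty;
#'   genes absent from the matrix are ignored).
#' @return tibble `barcode_id`, `library_id`, `nUMI`, `nFEA`, `pMT`.
#' @export
compute_cell_metrics <- function(m, mito_gene_set) {
  stopifnot(length(mito_gene_set) >= 1)
  numi <- Matrix::colSums(m$values)
  nfea <- Matrix::colSums(m$values > 0)
  mito <- intersect(mito_gene_set, m$gene_ids)
  mito_umi <- if (length(mito))
    Matrix::colSums(m$values[mito, , drop = FALSE]) else numeric(ncol(m$values))
  pmt <- ifelse(numi > 0, 100 * mito_umi / numi, 0)
  if (any(numi == 0)) warning("zero-total droplet(s): pMT set to 0")
  tibble::tibble(barcode_id = m$barcode_ids, library_id = m$library_id,
                 nUMI = as.numeric(numi), nFEA = as.numeric(nfea),
                 pMT = as.numeric(pmt))
}

#' QC metrics for several libraries at once
#' @param mats named list of [counts_matrix()].
#' @param mito_genes mitochondrial gene ids.
#' @return row-bound tibble of [compute_cell_metrics()] results.
#' @export
compute_cell_metrics_multi <- function(mats, mito_genes) {
  dplyr::bind_rows(lapply(mats, compute_cell_metrics,
                          mito_gene_set = mito_genes))
}

#' Preliminary droplet filter
#'
#' First-pass cleaning: drop droplets with `nFEA <= 500` or `nUMI <= 1000` or
#' `pMT >= 50%` (boundaries inclusive exactly as stated).
#'
#' @param cells metrics tibble from [compute_cell_metrics()].
#' @param th a [qc_thresholds()].
#' @return `cells` with logical `filtered` and character `reason` columns
#'   (comma-joined reason codes).
#' @export
preliminary_filter <- function(cells, th = qc_thresholds()) {
  r_nfea <- cells$nFEA <= th$prelim_nfea
  r_numi <- cells$nUMI <= th$prelim_numi
  r_pmt <- cells$pMT >= th$prelim_pmt
  reason <- purrr::pmap_chr(list(r_nfea, r_numi, r_pmt), function(a, b, c) {
    r <- c("low_nfea", "low_numi", "high_pmt")[c(a, b, c)]
    if (length(r)) paste(r, collapse = ",") else NA_character_
  })
  cells |>
    dplyr::mutate(filtered = r_nfea | r_numi | r_pmt, reason = reason)
}

#' Score droplets against simulated doublets
#'
#' Generates `ceiling(pN * C)` artificial doublets as averages of two random
#' cells' normalized profiles, co-embeds observed and artificial droplets in
#' `nPC` principal components, and scores each observed cell by the fraction
#' of artificial doublets among its `ceiling(pK * (C + C_art))` Euclidean
#' nearest neighbours. Two scorers flag doublets: `threshold` (score >
#' `sim_threshold`) and `quantile` (top `nExp` fraction of scores, stable
#' order on ties); the consensus is their intersection.
#'
#' @param nm normalized genes-by-cells matrix (see [lognormalize()]), dense or
#'   sparse, with column names.
#' @param th a [qc_thresholds()].
#' @param seed seed for artificial-pair sampling.
#' @return tibble `barcode_id`, `score`, `flag_threshold`, `flag_quantile`,
#'   `consensus`.
#' @export
simulated_doublet_scores <- function(nm, th = qc_thresholds(), seed = 1) {
  nm <- as.matrix(nm)
  C <- ncol(nm)
  if (C < 20) stop("need at least 20 cells to score doublets", call. = FALSE)
  if (th$pN <= 0) stop("pN must be positive (no artificial doublets)",
                       call. = FALSE)
  set.seed(seed)
  n_art <- ceiling(th$pN * C)
  i1 <- sample.int(C, n_art, replace = TRUE)
  i2 <- sample.int(C, n_art, replace = TRUE)
  art <- (nm[, i1, drop = FALSE] + nm[, i2, drop = FALSE]) / 2
  comb <- cbind(nm, art)
  k <- ceiling(th$pK * ncol(comb))
  if (ncol(comb) <= k) stop("fewer droplets than neighborhood size",
                            call. = FALSE)
  pcs <- .pca_embed(t(comb), n_pcs = th$nPC)$x
  d <- as.matrix(stats::dist(pcs))
  is_art <- c(rep(FALSE, C), rep(TRUE, n_art))
  score <- vapply(seq_len(C), function(i) {
    nn <- order(d[i, -i])[seq_len(k)]
    idx <- seq_len(ncol(comb))[-i][nn]
    mean(is_art[idx])
  }, numeric(1))
  flag_thr <- score > th$sim_threshold
  n_top <- ceiling(th$nExp * C)
  flag_q <- logical(C)
  flag_q[order(-score)[seq_len(n_top)]] <- TRUE
  tibble::tibble(barcode_id = colnames(nm), score = score,
                 flag_threshold = flag_thr, flag_quantile = flag_q,
                 consensus = flag_thr & flag_q)
}

#' Consensus of two doublet scorers
#' @param scores output of [simulated_doublet_scores()] (or any tibble with
#'   `flag_threshold` and `flag_quantile`).
#' @return the tibble with `consensus` recomputed as the intersection.
#' @export
consensus_doublets <- function(scores) {
  dplyr::mutate(scores, consensus = flag_threshold & flag_quantile)
}

#' Adaptive per-library feature-count cutoff
#'
#' Uses the default cutoff (`nFEA < 1400`) unless the flagged cells enrich an
#' exocrine-annotated (acinar/ductal) cluster - operationalized as more than
#' `exocrine_enrich_frac` (default 50%) of such a cluster falling under the
#' default cutoff - in which case the relaxed cutoff (`nFEA < 1000`) applies.
#'
#' @param cells metrics tibble with a `cluster` column.
#' @param annotations tibble `cluster`, `cell_type` (provisional annotation).
#' @param th a [qc_thresholds()].
#' @return list `cutoff` (numeric) and `trigger` (the exocrine cluster that
#'   relaxed it, or `NA`).
#' @export
adaptive_nfea_threshold <- function(cells, annotations, th = qc_thresholds()) {
  if (is.null(annotations) || !nrow(annotations)) {
    warning("no cluster annotation; using default nFEA cutoff")
    return(list(cutoff = th$nfea_default, trigger = NA_integer_))
  }
  exo <- annotations$cluster[annotations$cell_type %in% c("acinar", "ductal")]
  frac_under <- cells |>
    dplyr::filter(cluster %in% exo) |>
    dplyr::group_by(cluster) |>
    dplyr::summarise(frac = mean(nFEA < th$nfea_default), .groups = "drop")
  hit <- frac_under |> dplyr::filter(frac > th$exocrine_enrich_frac)
  if (nrow(hit))
    list(cutoff = th$nfea_relaxed, trigger = hit$cluster[1])
  else list(cutoff = th$nfea_default, trigger = NA_integer_)
}

# Tukey-Kramer pairwise comparisons via the studentized range
.tukey_pairs <- function(values, groups) {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  df <- length(values) - k
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df
  pairs <- utils::combn(levels(groups), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    diff <- m[b] - m[a]
    se <- sqrt(mse / 2 * (1 / n[a] + 1 / n[b]))
    q <- abs(diff) / se
    tibble::tibble(group1 = a, group2 = b, diff = unname(diff),
                   p = unname(stats::ptukey(q, k, df, lower.tail = FALSE)))
  })
}

#' Group comparison of per-donor pMT quantiles
#'
#' The unit of analysis is the per-donor quantile of the pMT distribution
#' (using cells directly would pseudo-replicate). For each requested quantile
#' a one-way ANOVA across groups is run on the per-donor values, followed by
#' Tukey HSD pairwise tests; p-values are Bonferroni-corrected across
#' quantiles.
#'
#' @param cells tibble with `pMT`, `donor_id` and the grouping column.
#' @param grouping column name to compare across (`"cell_type"` or `"state"`).
#' @param quantiles percent quantiles of pMT used as donor-level summaries.
#' @param alpha significance level applied after correction.
#' @return list `anova` (tibble per quantile) and `pairs` (tibble of pairwise
#'   Tukey results with `p_bonf` and `significant`).
#' @export
group_pmt_comparison <- function(cells, grouping = "cell_type",
                                 quantiles = c(50, 70, 90), alpha = 0.05) {
  cells$group <- cells[[grouping]]
  donor_q <- cells |>
    dplyr::filter(!is.na(group), !is.na(donor_id)) |>
    dplyr::group_by(group, donor_id) |>
    dplyr::summarise(q = list(stats::quantile(pMT, quantiles / 100)),
                     .groups = "drop") |>
    tidyr::unnest_longer(q, indices_to = "quantile") |>
    dplyr::mutate(quantile = quantiles[match(quantile,
                                             paste0(quantiles, "%"))])
  keep <- donor_q |>
    dplyr::count(group, quantile) |>
    dplyr::filter(n >= 2)
  dropped <- setdiff(unique(donor_q$group), unique(keep$group))
  if (length(dropped))
    warning("group(s) with a single donor excluded: ",
            paste(dropped, collapse = ", "))
  donor_q <- dplyr::semi_join(donor_q, keep, by = c("group", "quantile"))
  nq <- length(quantiles)
  res_a <- list(); res_p <- list()
  for (qq in quantiles) {
    d <- donor_q[donor_q$quantile == qq, ]
    if (dplyr::n_distinct(d$group) < 2) next
    fit <- stats::aov(q ~ group, data = d)
    s <- summary(fit)[[1]]
    res_a[[as.character(qq)]] <- tibble::tibble(
      quantile = qq, F = s$`F value`[1], p = s$`Pr(>F)`[1])
    res_p[[as.character(qq)]] <- .tukey_pairs(d$q, d$group) |>
      dplyr::mutate(quantile = qq, .before = 1)
  }
  pairs <- dplyr::bind_rows(res_p) |>
    dplyr::mutate(p_bonf = pmin(1, p * nq), significant = p_bonf <= alpha)
  list(anova = dplyr::bind_rows(res_a), pairs = pairs)
}

#' Annotation-aware mitochondrial filter
#'
#' After cell types are final, beta cells are dropped at `pMT >= 40%` and all
#' other (or unannotated) cell types at `pMT >= 20%`.
#'
#' @param cells tibble with `cell_type` and `pMT`.
#' @param th a [qc_thresholds()].
#' @return `cells` with `filtered`/`reason` updated (reason
#'   `celltype_pmt`).
#' @export
annotation_aware_filter <- function(cells, th = qc_thresholds()) {
  unknown <- is.na(cells$cell_type) |
    !(cells$cell_type %in% c("beta", names(th$celltype_pmt)))
  if (any(unknown & !is.na(cells$cell_type) &
            !cells$cell_type %in% c("beta")))
    warning("unknown cell type treated as 'other'")
  cut <- ifelse(!is.na(cells$cell_type) & cells$cell_type == "beta",
                th$celltype_pmt[["beta"]], th$celltype_pmt[["other"]])
  hit <- cells$pMT >= cut
  cells |>
    dplyr::mutate(
      filtered = dplyr::coalesce(filtered, FALSE) | hit,
      reason = dplyr::case_when(
        hit & is.na(reason) ~ "celltype_pmt",
        hit ~ paste(reason, "celltype_pmt", sep = ","),
        TRUE ~ reason))
}
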
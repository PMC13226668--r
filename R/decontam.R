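#' Estimate the ambient "soup" expression profile from empty droplets
#'
#' Droplets whose total UMI count is strictly below `empty_threshold` are
#' treated as cell-free, and the background fraction of each gene is the
#' pooled count share across them:
#' `b_g = sum_e n_ge / sum_e sum_g n_ge`.
#'
#' @param raw a [counts_matrix()] holding the unfiltered (raw) droplets.
#' @param empty_threshold UMI cutoff; droplets with totals `< empty_threshold`
#'   define the soup (default 10).
#' @return list of class `soup_profile`: `b` (named simplex over genes),
#'   `empty_threshold`, `n_empty`.
#' @export
estimate_soup_profile <- function(raw, empty_threshold = 10) {
  tot <- droplet_totals(raw)
  empties <- which(tot < empty_threshold)
  if (!length(empties))
    stop("no droplets with total UMIs < ", empty_threshold,
         "; raise empty_threshold", call. = FALSE)
  pooled <- Matrix::rowSums(raw$values[, empties, drop = FALSE])
  if (sum(pooled) == 0)
    stop("all empty droplets have zero counts; raise empty_threshold",
         call. = FALSE)
  structure(list(b = pooled / sum(pooled),
                 empty_threshold = empty_threshold,
                 n_empty = length(empties)),
            class = "soup_profile")
}

#' @export
print.soup_profile <- function(x, ...) {
  top <- utils::head(sort(x$b, decreasing = TRUE), 5)
  cat(sprintf("<soup_profile> %d empty droplets (< %d UMIs); top genes: %s\n",
              x$n_empty, x$empty_threshold,
              paste(names(top), collapse = ", ")))
  invisible(x)
}

#' Estimate per-cell contamination fractions
#'
#' Cluster-level unexpressed-gene estimator. For each cluster, genes whose
#' within-cluster count share is far below their soup share (bottom decile of
#' the ratio share/b, and share below `share_max` times `b_g`) are taken as
#' endogenously unexpressed; their observed counts are attributed to soup.
#' The cluster estimate aggregates per-cell ratios
#' `sum_{g in S_x} n_gc / (N_c * sum_{g in S_x} b_g)`, by default through the
#' cluster median (robust to the heterotypic-doublet minority, which carries
#' other types' markers endogenously); `aggregate = "pooled"` instead uses
#' the pooled-count ratio
#' `clip( sum_c sum_g n_gc / sum_c N_c * sum_g b_g, 0, 1)`.
#' Every cell inherits its cluster's estimate. `method = "fixed"` applies a
#' single user-supplied fraction instead.
#'
#' @param filtered [counts_matrix()] of cell-containing droplets.
#' @param soup a `soup_profile`.
#' @param clusters per-cell cluster labels (length = droplets).
#' @param method `"unexpressed_gene"` (default) or `"fixed"`.
#' @param fixed_rho required when `method = "fixed"`.
#' @param min_expected detectability floor: a gene is a selection candidate
#'   only when `N_x * b_g >= min_expected` (expected soup counts large enough
#'   that a low observed ratio is evidence, not a sampling zero).
#' @param share_max selection ceiling: within-cluster count share must stay
#'   below `share_max * b_g` for a gene to count as plausibly unexpressed.
#' @param gene_sets optional named list (cluster -> gene ids) overriding the
#'   automatic selection, e.g. for known-exclusive marker sets.
#' @param aggregate `"median"` (default, robust) or `"pooled"` per-cluster
#'   aggregation of the soup-share ratios.
#' @return list of class `contamination_estimate`: `rho` (per cell, named by
#'   barcode), `cluster_rho` tibble, `method`.
#' @export
estimate_contamination <- function(filtered, soup, clusters,
                                   method = c("unexpressed_gene", "fixed"),
                                   fixed_rho = NULL, min_expected = 250,
                                   share_max = 0.25, gene_sets = NULL,
                                   aggregate = c("median", "pooled")) {
  aggregate <- match.arg(aggregate)
  method <- match.arg(method)
  n_cells <- ncol(filtered$values)
  if (method == "fixed") {
    if (is.null(fixed_rho)) stop("method='fixed' requires fixed_rho",
                                 call. = FALSE)
    rho <- rep(fixed_rho, n_cells)
    names(rho) <- filtered$barcode_ids
    return(structure(list(rho = rho, method = method,
                          cluster_rho = tibble::tibble(
                            cluster = NA_integer_, rho = fixed_rho)),
                     class = "contamination_estimate"))
  }
  stopifnot(length(clusters) == n_cells)
  b <- soup$b[filtered$gene_ids]
  tot <- droplet_totals(filtered)
  cl_levels <- sort(unique(clusters))
  cluster_rho <- numeric(length(cl_levels))
  select_genes <- function(share, N_x) {
    cand <- which(b * N_x >= min_expected)
    if (!length(cand)) return(integer(0))
    ratio <- share[cand] / b[cand]
    dec <- stats::quantile(ratio, 0.1)
    cand[ratio <= dec & share[cand] < share_max * b[cand]]
  }
  # global fallback set from the pooled profile
  pooled <- Matrix::rowSums(filtered$values)
  sel_global <- select_genes(pooled / sum(pooled), sum(pooled))
  for (i in seq_along(cl_levels)) {
    idx <- which(clusters == cl_levels[i])
    cl_counts <- Matrix::rowSums(filtered$values[, idx, drop = FALSE])
    share <- cl_counts / sum(cl_counts)
    S <- if (!is.null(gene_sets))
      match(gene_sets[[as.character(cl_levels[i])]], filtered$gene_ids)
    else select_genes(share, sum(cl_counts))
    if (!length(S)) {
      warning("cluster ", cl_levels[i],
              ": no plausibly unexpressed genes; using global set")
      S <- sel_global
    }
    if (!length(S)) {
      cluster_rho[i] <- NA_real_
      next
    }
    if (aggregate == "pooled") {
      num <- sum(cl_counts[S])
      den <- sum(tot[idx]) * sum(b[S])
      cluster_rho[i] <- min(max(num / den, 0), 1)
    } else {
      per_cell <- Matrix::colSums(filtered$values[S, idx, drop = FALSE]) /
        (tot[idx] * sum(b[S]))
      cluster_rho[i] <- min(max(stats::median(per_cell), 0), 1)
    }
  }
  if (anyNA(cluster_rho)) {
    if (all(is.na(cluster_rho)))
      stop("no cluster yields an unexpressed gene set; use method='fixed'",
           call. = FALSE)
    warning("cluster(s) without a usable gene set received the mean of ",
            "the estimated clusters")
    cluster_rho[is.na(cluster_rho)] <- mean(cluster_rho, na.rm = TRUE)
  }
  rho <- cluster_rho[match(clusters, cl_levels)]
  names(rho) <- filtered$barcode_ids
  structure(list(rho = rho, method = method,
                 cluster_rho = tibble::tibble(cluster = cl_levels,
                                              rho = cluster_rho)),
            class = "contamination_estimate")
}

#' Subtract expected soup counts from each cell
#'
#' Decontaminated counts follow `n~_gc = n_gc - N_c * rho_c * b_g`, optionally
#' clipped at zero. Without clipping the per-cell mass identity
#' `sum_g n~_gc = N_c (1 - rho_c)` holds exactly.
#'
#' @param filtered [counts_matrix()] of cells.
#' @param soup a `soup_profile`.
#' @param est a `contamination_estimate` covering every cell.
#' @param clip_negative clip negative corrected values to zero (default TRUE).
#' @return a float-valued [counts_matrix()] (`integral = FALSE`).
#' @export
correct_counts <- function(filtered, soup, est, clip_negative = TRUE) {
  stopifnot(ncol(filtered$values) == length(est$rho))
  b <- soup$b[filtered$gene_ids]
  if (anyNA(b)) stop("soup profile does not cover every gene", call. = FALSE)
  tot <- droplet_totals(filtered)
  expected <- outer(as.numeric(b), as.numeric(tot * est$rho))
  corrected <- as.matrix(filtered$values) - expected
  if (clip_negative) {
    corrected[corrected < 0] <- 0
    return(counts_matrix(corrected, filtered$gene_ids,
                         filtered$barcode_ids, filtered$library_id,
                         integral = FALSE))
  }
  # the unclipped diagnostic matrix may hold negatives; bypass the
  # non-negativity contract of the public constructor
  v <- methods::as(Matrix::Matrix(corrected, sparse = TRUE),
                   "CsparseMatrix")
  dimnames(v) <- list(filtered$gene_ids, filtered$barcode_ids)
  structure(list(values = v, gene_ids = filtered$gene_ids,
                 barcode_ids = filtered$barcode_ids,
                 library_id = filtered$library_id, integral = FALSE),
            class = "counts_matrix")
}

#' Per-gene decontamination assessment across libraries
#'
#' For each gene g and library j let `M_g^j` be the difference between the
#' library's average uncorrected and corrected UMI count. Reported are the
#' across-library means `M_g`, the average expression level
#' `A_g = mean_j (Ubar + Cbar)` (the MA-plot abscissa), and the mean
#' contamination rank `r_g = mean_j rank(M_g^j)` with rank 1 the largest
#' removal; ties take average ranks.
#'
#' @param uncorrected,corrected named lists of [counts_matrix()] keyed by
#'   library; both must cover the same libraries.
#' @return tibble `gene_id`, `M`, `A`, `rank`.
#' @export
assess_decontamination <- function(uncorrected, corrected) {
  libs <- names(uncorrected)
  if (!setequal(libs, names(corrected)))
    stop("library present in only one matrix set", call. = FALSE)
  genes <- uncorrected[[1]]$gene_ids
  J <- length(libs)
  Ms <- matrix(0, length(genes), J)
  As <- matrix(0, length(genes), J)
  Rs <- matrix(0, length(genes), J)
  for (j in seq_along(libs)) {
    u <- Matrix::rowMeans(uncorrected[[libs[j]]]$values)
    co <- Matrix::rowMeans(corrected[[libs[j]]]$values)
    Ms[, j] <- u - co
    As[, j] <- (u + co) / 2
    Rs[, j] <- rank(-Ms[, j], ties.method = "average")
  }
  tibble::tibble(gene_id = genes, M = rowMeans(Ms), A = rowMeans(As),
                 rank = rowMeans(Rs))
}

#' MA-style plot of decontamination effect
#' @param assessment output of [assess_decontamination()].
#' @param label_top label this many top-ranked contaminants.
#' @return a ggplot.
#' @export
plot_decontamination <- function(assessment, label_top = 10) {
  top <- assessment |> dplyr::slice_min(rank, n = label_top)
  ggplot2::ggplot(assessment, ggplot2::aes(x = A, y = M)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = top, colour = "firebrick") +
    ggplot2::geom_text(data = top, ggplot2::aes(label = gene_id),
                       vjust = -0.6, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean of corrected and uncorrected average UMI (A)",
                  y = "average UMI removed (M)") +
    ggplot2::theme_minimal()
}
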
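#' Residualize expression on nuisance covariates
#'
#' Per gene, ordinary least squares of expression on the covariates (disease
#' state excluded); returns residuals plus the gene's grand mean, so the
#' expression scale is preserved while every covariate direction is removed
#' exactly (residuals are orthogonal to each covariate column).
#'
#' @param expr samples-by-genes matrix (e.g. log2 CPM pseudobulk).
#' @param covariates data frame of nuisance covariates (scaled age, sex,
#'   scaled BMI, ancestry, chemistry); constant columns are dropped.
#' @return residualized matrix of the same shape.
#' @export
residualize_covariates <- function(expr, covariates) {
  covariates <- as.data.frame(covariates)
  keep <- vapply(covariates, function(v) dplyr::n_distinct(v) > 1, logical(1))
  if (!any(keep)) return(expr)
  X <- stats::model.matrix(~ ., data = covariates[, keep, drop = FALSE])
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate design",
                                 call. = FALSE)
  H <- X %*% solve(crossprod(X), t(X))
  res <- expr - H %*% expr
  sweep(res, 2, colMeans(expr), "+")
}

#' Genes expressed in enough donors
#'
#' Co-expression input filter: keep genes with a nonzero pseudobulk count in
#' more than `min_donors` donors.
#'
#' @param counts genes-by-samples pseudobulk count matrix.
#' @param min_donors strict lower bound on expressing donors (default 20).
#' @return character vector of retained gene ids.
#' @export
filter_expressed_genes <- function(counts, min_donors = 20) {
  rownames(counts)[rowSums(counts > 0) > min_donors]
}

#' Soft-threshold scan for scale-free topology
#'
#' For each power `t` in the grid the signed adjacency
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^t` is formed, connectivities
#' `k_i = sum_{j != i} a_ij` computed, and the scale-free fit is the R^2 of
#' the regression of `log10 p(k)` on `log10 k` over 10 connectivity bins,
#' sign-flipped negative when the slope is positive. Constant genes are
#' excluded with a warning.
#'
#' @param expr samples-by-genes matrix.
#' @param grid integer powers to scan (default 1:20).
#' @param n_bins connectivity histogram bins (default 10).
#' @return tibble `power`, `sft_r2`, `mean_connectivity`.
#' @export
soft_threshold_scan <- function(expr, grid = 1:20, n_bins = 10) {
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) excluded")
    expr <- expr[, sds > 0, drop = FALSE]
  }
  if (ncol(expr) < 30) stop("need at least 30 genes", call. = FALSE)
  cors <- stats::cor(expr)
  base <- (1 + cors) / 2
  diag(base) <- 0
  purrr::map_dfr(grid, function(t) {
    a <- base^t
    diag(a) <- 0
    k <- colSums(a)
    tibble::tibble(power = t, sft_r2 = .scale_free_r2(k, n_bins),
                   mean_connectivity = mean(k))
  })
}

.scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  mid <- (br[-1] + br[-length(br)]) / 2
  ok <- !is.na(pk) & pk > 0
  if (sum(ok) < 3) return(0)
  f <- stats::lm(log10(pk[ok]) ~ log10(mid[ok]))
  r2 <- summary(f)$r.squared
  if (stats::coef(f)[2] > 0) -r2 else r2
}

#' Signed adjacency at a chosen power
#' @param expr samples-by-genes matrix.
#' @param power soft threshold (default 12).
#' @return genes-by-genes adjacency in `[0, 1]`, zero diagonal.
#' @export
signed_adjacency <- function(expr, power = 12) {
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) excluded from the network")
    expr <- expr[, sds > 0, drop = FALSE]
  }
  a <- ((1 + stats::cor(expr)) / 2)^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj`; the diagonal is 1. The TOM-based dissimilarity
#' is `1 - TOM`.
#'
#' @param adjacency symmetric matrix with zero diagonal, entries in `[0, 1]`.
#' @return the TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  if (max(abs(adjacency - t(adjacency))) > 1e-10)
    stop("adjacency is not symmetric", call. = FALSE)
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a
  k <- colSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector along the
#' samples of the module's standardized expression, sign-oriented to
#' correlate positively with the module's mean expression profile, and
#' unit-norm.
#'
#' @param expr samples-by-genes matrix.
#' @param modules named module labels per gene (character; `"grey"` =
#'   unassigned, excluded).
#' @return samples x modules matrix of eigengenes.
#' @export
module_eigengene <- function(expr, modules) {
  mods <- setdiff(unique(modules), "grey")
  out <- vapply(mods, function(m) {
    sub <- scale(expr[, modules == m, drop = FALSE])
    sub[, attr(sub, "scaled:scale") == 0] <- 0
    sv <- svd(sub, nu = 1, nv = 0)
    e <- sv$u[, 1]
    if (stats::cor(e, rowMeans(sub)) < 0) e <- -e
    e
  }, numeric(nrow(expr)))
  matrix(out, nrow = nrow(expr), dimnames = list(rownames(expr), mods))
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on the dissimilarity; an initial
#' fixed-height cut at `cut_frac` of the maximal join height, branches below
#' `min_module_size` sent to grey; then iterative eigengene merging: modules
#' whose eigengene dissimilarity `1 - cor` falls below `merge_cut_height`
#' are merged until a fixed point.
#'
#' @param diss genes-by-genes TOM dissimilarity (`1 - TOM`).
#' @param expr samples-by-genes matrix (for eigengene merging).
#' @param min_module_size smallest retained module (default 100).
#' @param merge_cut_height eigengene-dissimilarity merge threshold
#'   (default 0.25).
#' @param cut_frac fraction of the maximal join height for the initial cut.
#' @return list of class `module_partition`: `modules` (named labels,
#'   `"M1"`... by decreasing size, `"grey"` unassigned), `eigengenes`,
#'   `dendrogram`.
#' @export
detect_modules <- function(diss, expr, min_module_size = 100,
                           merge_cut_height = 0.25, cut_frac = 0.90) {
  stopifnot(nrow(diss) == ncol(diss), nrow(diss) == ncol(expr))
  genes <- colnames(expr)
  if (nrow(diss) < min_module_size) {
    modules <- stats::setNames(rep("grey", length(genes)), genes)
    return(structure(list(modules = modules, eigengenes = NULL,
                          dendrogram = NULL), class = "module_partition"))
  }
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  hc$height <- cummax(hc$height)   # guard against tiny numeric inversions
  lab <- stats::cutree(hc, h = cut_frac * max(hc$height))
  sizes <- table(lab)
  lab <- ifelse(lab %in% as.integer(names(sizes)[sizes >= min_module_size]),
                as.character(lab), "grey")
  repeat {
    mods <- setdiff(unique(lab), "grey")
    if (length(mods) < 2) break
    eg <- module_eigengene(expr, lab)
    ediss <- 1 - stats::cor(eg)
    diag(ediss) <- Inf
    hit <- which(ediss == min(ediss), arr.ind = TRUE)[1, ]
    if (min(ediss) >= merge_cut_height) break
    lab[lab == colnames(ediss)[hit[2]]] <- rownames(ediss)[hit[1]]
  }
  mods <- setdiff(unique(lab), "grey")
  ord <- names(sort(table(lab[lab != "grey"]), decreasing = TRUE))
  relabel <- stats::setNames(paste0("M", seq_along(ord)), ord)
  modules <- ifelse(lab == "grey", "grey", relabel[lab])
  names(modules) <- genes
  eg <- if (length(mods)) module_eigengene(expr, modules) else NULL
  structure(list(modules = modules, eigengenes = eg, dendrogram = hc),
            class = "module_partition")
}

#' Module-trait Spearman correlation
#'
#' Spearman correlation (with asymptotic p) between each module eigengene and
#' each trait; binary traits are coded 0/1 by the caller. Constant traits
#' give `NA` with a warning.
#'
#' @param eigengenes samples x modules matrix.
#' @param traits data frame of per-sample traits.
#' @param alpha significance level for the `significant` mark.
#' @return tibble `module`, `trait`, `rho`, `p`, `significant`.
#' @export
module_trait_correlation <- function(eigengenes, traits, alpha = 0.05) {
  traits <- as.data.frame(traits)
  purrr::map_dfr(colnames(eigengenes), function(m) {
    purrr::map_dfr(names(traits), function(tr) {
      y <- traits[[tr]]
      if (dplyr::n_distinct(y[!is.na(y)]) < 2) {
        warning("constant trait: ", tr)
        return(tibble::tibble(module = m, trait = tr, rho = NA_real_,
                              p = NA_real_, significant = NA))
      }
      ct <- suppressWarnings(stats::cor.test(eigengenes[, m], y,
                                             method = "spearman"))
      tibble::tibble(module = m, trait = tr, rho = unname(ct$estimate),
                     p = ct$p.value, significant = ct$p.value <= alpha)
    })
  })
}

#' Heatmap of module-trait correlations
#' @param mt output of [module_trait_correlation()].
#' @return a ggplot.
#' @export
plot_module_trait <- function(mt) {
  ggplot2::ggplot(mt, ggplot2::aes(trait, module, fill = rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = dplyr::case_when(
      is.na(p) ~ "", p <= 0.001 ~ "**", p <= 0.05 ~ "*", TRUE ~ "")),
      size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  high = "firebrick") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
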
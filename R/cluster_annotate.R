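#' Library-size log-normalization
#'
#' `x_gc = ln(1 + scale_factor * n_gc / N_c)`; columns with zero totals map to
#' zeros. Doubling a cell's counts leaves its normalized vector unchanged
#' (per-cell compositional property).
#'
#' @param m a [counts_matrix()] or genes-by-cells matrix.
#' @param scale_factor global scaling constant (default 10,000).
#' @return dense genes-by-cells matrix of normalized values.
#' @export
lognormalize <- function(m, scale_factor = 10000) {
  v <- if (inherits(m, "counts_matrix")) m$values else m
  tot <- Matrix::colSums(v)
  sc <- ifelse(tot > 0, scale_factor / tot, 0)
  out <- as.matrix(v %*% Matrix::Diagonal(x = sc))
  dimnames(out) <- dimnames(v)
  log1p(out)
}

#' Highly variable gene selection
#'
#' Ranks genes by variance standardized against a mean-variance trend: genes
#' are binned by normalized mean expression, the trend is the rolling median
#' of within-bin variances, and each gene's variance is divided by its bin's
#' trend value. Constant genes score zero. Ties break deterministically by
#' gene id.
#'
#' @param nm normalized genes-by-cells matrix.
#' @param n number of genes to keep.
#' @param n_bins bins of the mean-variance trend.
#' @return character vector of `n` gene ids, most variable first.
#' @export
select_hvg <- function(nm, n = 2000, n_bins = 20) {
  if (n > nrow(nm)) stop("n exceeds gene count", call. = FALSE)
  mu <- rowMeans(nm)
  v <- apply(nm, 1, stats::var)
  bin <- ggplot2::cut_number(rank(mu, ties.method = "first"),
                             n = min(n_bins, max(1, floor(nrow(nm) / 5))))
  trend <- stats::ave(v, bin, FUN = stats::median)
  std_var <- ifelse(v > 0, v / pmax(trend, .Machine$double.eps), 0)
  ord <- order(-std_var, rownames(nm))
  rownames(nm)[ord][seq_len(n)]
}

# centered/scaled PCA via the smaller-side eigendecomposition;
# sign convention: the largest-magnitude loading of each PC is positive
.pca_embed <- function(X, n_pcs) {
  X <- scale(X)
  X[, attr(X, "scaled:scale") == 0] <- 0
  n <- nrow(X); p <- ncol(X)
  n_pcs <- min(n_pcs, n - 1, p)
  if (n <= p) {
    K <- tcrossprod(X)
    eig <- eigen(K, symmetric = TRUE)
    keep <- which(eig$values > 1e-9)[seq_len(min(n_pcs, sum(eig$values > 1e-9)))]
    d <- sqrt(eig$values[keep])
    U <- eig$vectors[, keep, drop = FALSE]
    scores <- U %*% diag(d, length(d))
    rot <- crossprod(X, U) %*% diag(1 / d, length(d))
  } else {
    K <- crossprod(X)
    eig <- eigen(K, symmetric = TRUE)
    keep <- which(eig$values > 1e-9)[seq_len(min(n_pcs, sum(eig$values > 1e-9)))]
    rot <- eig$vectors[, keep, drop = FALSE]
    scores <- X %*% rot
    d <- sqrt(eig$values[keep])
  }
  flip <- apply(rot, 2, function(col) sign(col[which.max(abs(col))]))
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  total_var <- sum(apply(X, 2, stats::var)) * (n - 1)
  list(x = scores, rotation = rot, sdev = d / sqrt(max(n - 1, 1)),
       explained = d^2 / total_var)
}

#' PCA embedding of normalized expression
#'
#' Genes are centered and unit-scaled before a truncated SVD. If the matrix
#' rank is below `n_pcs`, fewer components are returned with a warning.
#'
#' @param nm normalized genes-by-cells matrix (restrict to HVG first).
#' @param n_pcs components to keep (100 whole-atlas, 20 for subclustering).
#' @return list of class `embedding`: `x` (cells x PCs), `rotation`, `sdev`,
#'   `explained`, `hvg`.
#' @export
embed_pca <- function(nm, n_pcs = 100) {
  if (n_pcs > min(dim(nm)))
    stop("n_pcs exceeds min(genes, cells)", call. = FALSE)
  res <- .pca_embed(t(nm), n_pcs)
  if (ncol(res$x) < n_pcs)
    warning("rank-deficient input: returning ", ncol(res$x), " PCs")
  rownames(res$x) <- colnames(nm)
  res$hvg <- rownames(nm)
  class(res) <- "embedding"
  res
}

#' Iterative covariate alignment in PC space
#'
#' Soft k-means batch alignment: cells are softly assigned to `k` clusters in
#' PC space; per iteration and per covariate, each covariate level's
#' responsibility-weighted centroid offset from the cluster centroid is
#' subtracted from that level's cells. Balanced covariates yield a near-zero
#' correction; covariate levels with fewer than 5 cells are merged into
#' "other".
#'
#' @param e an `embedding` (see [embed_pca()]).
#' @param covariates data frame of per-cell categorical covariates (e.g. sex,
#'   chemistry, ancestry).
#' @param k soft k-means clusters.
#' @param n_iter maximum iterations (default 10).
#' @param tol stop when the total correction norm falls below `tol`.
#' @param seed seed for centroid initialization.
#' @return the embedding with aligned `x`.
#' @export
covariate_align <- function(e, covariates, k = 30, n_iter = 10, tol = 1e-4,
                            seed = 1) {
  X <- e$x
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == nrow(X))
  for (j in seq_along(covariates)) {
    f <- factor(covariates[[j]])
    small <- names(which(table(f) < 5))
    if (length(small)) {
      warning("covariate level(s) with < 5 cells merged into 'other'")
      levels(f)[levels(f) %in% small] <- "other"
    }
    covariates[[j]] <- f
  }
  set.seed(seed)
  k <- min(k, nrow(X) - 1)
  centers <- X[sample.int(nrow(X), k), , drop = FALSE]
  sigma2 <- mean(apply(X, 2, stats::var))
  for (it in seq_len(n_iter)) {
    d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
      outer(rep(1, nrow(X)), rowSums(centers^2))
    r <- exp(-(d2 - apply(d2, 1, min)) / (2 * sigma2))
    r <- r / rowSums(r)
    total_corr <- 0
    corr <- matrix(0, nrow(X), ncol(X))
    for (j in seq_along(covariates)) {
      f <- droplevels(covariates[[j]])
      if (nlevels(f) < 2) next
      for (cl in seq_len(k)) {
        w <- r[, cl]
        if (sum(w) < 1e-8) next
        mu_all <- colSums(X * w) / sum(w)
        for (lev in levels(f)) {
          sel <- f == lev
          wl <- w[sel]
          if (sum(wl) < 1e-8) next
          off <- colSums(X[sel, , drop = FALSE] * wl) / sum(wl) - mu_all
          corr[sel, ] <- corr[sel, ] + outer(wl, off)
          total_corr <- total_corr + sqrt(sum(off^2)) * sum(wl) / sum(w)
        }
      }
    }
    X <- X - corr
    centers <- (t(r) %*% X) / colSums(r)
    if (total_corr < tol) break
  }
  e$x <- X
  e
}

#' Shared-nearest-neighbour graph clustering
#'
#' k-nearest neighbours by Euclidean distance in PC space; SNN edge weights
#' are the Jaccard overlap of neighbourhoods (self included), pruned below
#' `prune`; communities by seeded Louvain modularity optimization at the
#' given resolution. Labels are contiguous integers from 0 ordered by
#' decreasing cluster size.
#'
#' @param e an `embedding`, or a cells-by-dims matrix.
#' @param k neighbours (default 20).
#' @param resolution modularity resolution (1 atlas, 0.8 subclusters).
#' @param prune discard SNN weights below this (default 1/15).
#' @param seed clustering seed.
#' @return list of class `snn_clustering`: `labels` (named integer vector),
#'   `k`, `resolution`, `modularity`.
#' @export
snn_cluster <- function(e, k = 20, resolution = 1, prune = 1 / 15, seed = 1) {
  X <- if (inherits(e, "embedding")) e$x else as.matrix(e)
  n <- nrow(X)
  if (k >= n) stop("k must be below the number of cells", call. = FALSE)
  d <- as.matrix(stats::dist(X))
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k + 1)]))  # incl self
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1),
                            j = as.vector(t(nn)), x = 1,
                            dims = c(n, n))
  inter <- Matrix::tcrossprod(A)          # pairwise neighbourhood overlaps
  tri <- Matrix::summary(inter)
  tri <- tri[tri$i < tri$j, ]
  jac <- tri$x / (2 * (k + 1) - tri$x)
  keep <- jac >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = tri$i[keep], to = tri$j[keep], weight = jac[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  lab <- igraph::membership(comm)[as.character(seq_len(n))]
  sizes <- sort(table(lab), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relabel[as.character(lab)])
  names(labels) <- rownames(X)
  structure(list(labels = labels, k = k, resolution = resolution,
                 modularity = max(igraph::modularity(comm))),
            class = "snn_clustering")
}

#' Marker panel for islet cell types
#'
#' The canonical one-marker-per-type panel: beta INS, alpha GCG, delta SST,
#' gamma PPY, epsilon GHRL, ductal KRT19, acinar REG1B, stellate COL1A1,
#' quiescent stellate FABP4, endothelial PLVAP, Schwann NGFR, immune C1QC,
#' mast TPSB2, proliferating TOP2A.
#'
#' @return named character vector, cell type -> marker gene.
#' @export
marker_panel <- function() {
  c(beta = "INS", alpha = "GCG", delta = "SST", gamma = "PPY",
    epsilon = "GHRL", ductal = "KRT19", acinar = "REG1B",
    stellate = "COL1A1", quiescent_stellate = "FABP4",
    endothelial = "PLVAP", schwann = "NGFR", immune = "C1QC",
    mast = "TPSB2", proliferating = "TOP2A")
}

#' Marker-based cluster annotation
#'
#' Per cluster, each marker's mean normalized expression is z-scored across
#' clusters; the cluster takes the type of the maximal-z marker when that z
#' exceeds `z_min`, otherwise "unassigned". Clusters with two or more hormone
#' markers above `z_min` are additionally flagged multi-hormone
#' (doublet-suspect).
#'
#' @param clustering an `snn_clustering` or a named label vector.
#' @param nm normalized genes-by-cells matrix.
#' @param panel named character vector, type -> marker (see [marker_panel()]).
#' @param z_min minimal z-score for assignment (default 1).
#' @param hormones hormone genes for the multi-hormone flag.
#' @return tibble `cluster`, `cell_type`, `best_z`, `multi_hormone`.
#' @export
annotate_clusters <- function(clustering, nm, panel = marker_panel(),
                              z_min = 1,
                              hormones = c("INS", "GCG", "SST", "PPY",
                                           "GHRL")) {
  if (!length(panel)) stop("empty marker panel", call. = FALSE)
  labels <- if (inherits(clustering, "snn_clustering"))
    clustering$labels else clustering
  present <- panel[panel %in% rownames(nm)]
  missing <- setdiff(panel, present)
  if (length(missing))
    warning("markers absent from gene universe: ",
            paste(missing, collapse = ", "))
  if (!length(present)) stop("no panel markers present", call. = FALSE)
  cls <- sort(unique(labels))
  means <- vapply(cls, function(cl)
    rowMeans(nm[present, labels == cl, drop = FALSE]), numeric(length(present)))
  means <- matrix(means, nrow = length(present),
                  dimnames = list(names(present), cls))
  z <- t(scale(t(means)))
  z[is.nan(z)] <- 0
  horm <- intersect(rownames(nm)[rownames(nm) %in% hormones], present)
  horm_types <- names(present)[present %in% hormones]
  purrr::map_dfr(seq_along(cls), function(i) {
    zi <- z[, i]
    best <- which.max(zi)
    multi <- sum(zi[horm_types] > z_min) >= 2
    tibble::tibble(
      cluster = cls[i],
      cell_type = if (zi[best] > z_min) names(present)[best] else "unassigned",
      best_z = unname(zi[best]),
      multi_hormone = multi)
  })
}

# logistic IRLS with optional ridge penalty; returns deviance and coefficients
.logistic_fit <- function(X, y, lambda = 0, max_iter = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    H <- crossprod(X, X * w) + diag(lambda, ncol(X))
    beta_new <- solve(H, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  p <- 1 / (1 + exp(-drop(X %*% beta)))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  dev <- -2 * sum(y * log(p) + (1 - y) * log(1 - p))
  list(coef = drop(beta), deviance = dev)
}

#' One-vs-rest marker differential expression
#'
#' For each gene, membership in the target cluster is tested against the rest.
#' `family = "logistic"`: likelihood-ratio test of membership regressed on
#' covariates plus the gene's normalized expression versus covariates only
#' (1 df). `family = "negbinom"`: NB regression of raw counts on membership
#' plus covariates with a log-total offset, LRT on membership. log2FC is the
#' ratio of mean `expm1` normalized expression with pseudocount 1. BH FDR
#' across genes.
#'
#' @param nm normalized genes-by-cells matrix (logistic) or raw counts
#'   (negbinom; supply `nm` too for fold changes via `norm`).
#' @param labels per-cell cluster labels.
#' @param target target cluster label.
#' @param covariates data frame of per-cell covariates or `NULL`.
#' @param family `"logistic"` or `"negbinom"`.
#' @param norm normalized matrix for fold-change computation when `nm` holds
#'   counts.
#' @param min_cells minimal target-cluster size (default 10).
#' @param lfc_min,fdr_max reporting thresholds (defaults 0.25 and 0.01).
#' @return tibble `gene_id`, `log2fc`, `stat`, `p`, `fdr`, `flagged`
#'   (penalized fallback), `reported`.
#' @export
marker_de <- function(nm, labels, target, covariates = NULL,
                      family = c("logistic", "negbinom"), norm = NULL,
                      min_cells = 10, lfc_min = 0.25, fdr_max = 0.01) {
  family <- match.arg(family)
  y <- as.numeric(labels == target)
  if (sum(y) < min_cells)
    stop("target cluster below min_cells", call. = FALSE)
  Xc <- if (is.null(covariates)) matrix(1, ncol(nm), 1)
  else stats::model.matrix(~ ., data = as.data.frame(covariates))
  nmat <- if (is.null(norm)) nm else norm
  res <- purrr::map_dfr(rownames(nm), function(g) {
    expr <- nm[g, ]
    flagged <- FALSE
    if (family == "logistic") {
      f0 <- .logistic_fit(Xc, y)
      f1 <- withCallingHandlers(
        .logistic_fit(cbind(Xc, expr), y),
        warning = function(w) invokeRestart("muffleWarning"))
      if (any(!is.finite(f1$coef)) || max(abs(f1$coef)) > 30) {
        f0 <- .logistic_fit(Xc, y, lambda = 1e-4)
        f1 <- .logistic_fit(cbind(Xc, expr), y, lambda = 1e-4)
        flagged <- TRUE
      }
      stat <- max(f0$deviance - f1$deviance, 0)
    } else {
      tot <- colSums(nm)
      df <- data.frame(cnt = nm[g, ], member = y, off = log(pmax(tot, 1)))
      df <- cbind(df, as.data.frame(if (is.null(covariates))
        matrix(nrow = ncol(nm), ncol = 0) else covariates))
      full_form <- stats::as.formula(paste(
        "cnt ~ member + offset(off)",
        if (!is.null(covariates) && ncol(as.data.frame(covariates)))
          paste("+", paste(colnames(as.data.frame(covariates)),
                           collapse = " + ")) else ""))
      fit1 <- suppressWarnings(MASS::glm.nb(full_form, data = df))
      null_form <- stats::update(full_form, . ~ . - member)
      fit0 <- suppressWarnings(stats::glm(
        null_form, data = df,
        family = MASS::negative.binomial(fit1$theta)))
      stat <- max(fit0$deviance - fit1$deviance, 0)
    }
    mu_in <- mean(expm1(nmat[g, y == 1]))
    mu_out <- mean(expm1(nmat[g, y == 0]))
    tibble::tibble(gene_id = g, log2fc = log2((mu_in + 1) / (mu_out + 1)),
                   stat = stat,
                   p = stats::pchisq(stat, 1, lower.tail = FALSE),
                   flagged = flagged)
  })
  res |>
    dplyr::mutate(fdr = stats::p.adjust(p, "BH"),
                  reported = log2fc >= lfc_min & fdr <= fdr_max)
}
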
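#' Aggregate single cells into donor-by-cell-type pseudobulk
#'
#' Sums raw counts over all kept cells of each (donor, cell type) sample, so
#' donors - not cells - become the replication unit. Samples with fewer than
#' `min_cells` cells are dropped with a warning. The design table joins donor
#' covariates with age and BMI standardized over the retained samples.
#'
#' @param cells tibble of kept cells with `library_id`, `barcode_id`,
#'   `donor_id`, `cell_type`.
#' @param mats named list of [counts_matrix()] per library.
#' @param donors donor tibble (state, hba1c, age, bmi, sex, ancestry,
#'   chemistry).
#' @param min_cells minimum cells per pseudobulk sample (default 10).
#' @return list of class `pseudobulk`: `counts` (genes x samples),
#'   `design` tibble, `cells_per_sample`.
#' @export
aggregate_pseudobulk <- function(cells, mats, donors, min_cells = 10) {
  stopifnot(!anyNA(cells$donor_id), !anyNA(cells$cell_type))
  need <- c("state", "chemistry", "sex", "ancestry", "age", "bmi")
  miss <- need[!need %in% names(donors)]
  if (length(miss))
    stop("donor table lacks covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cells <- cells |>
    dplyr::mutate(sample_id = paste(donor_id, cell_type, sep = "."))
  genes <- mats[[1]]$gene_ids
  groups <- split(cells, cells$sample_id)
  agg <- vapply(groups, function(g) {
    tot <- numeric(length(genes))
    for (lib in unique(g$library_id)) {
      bc <- g$barcode_id[g$library_id == lib]
      tot <- tot + Matrix::rowSums(mats[[lib]]$values[, bc, drop = FALSE])
    }
    tot
  }, numeric(length(genes)))
  rownames(agg) <- genes
  n_cells <- vapply(groups, nrow, integer(1))
  small <- names(n_cells)[n_cells < min_cells]
  if (length(small)) {
    warning("dropping ", length(small), " pseudobulk sample(s) with < ",
            min_cells, " cells")
    agg <- agg[, !colnames(agg) %in% small, drop = FALSE]
    n_cells <- n_cells[!names(n_cells) %in% small]
  }
  design <- tibble::tibble(sample_id = colnames(agg)) |>
    tidyr::separate(sample_id, c("donor_id", "cell_type"), sep = "\\.",
                    remove = FALSE) |>
    dplyr::left_join(donors |> dplyr::select(dplyr::all_of(c("donor_id",
                                                             need, "hba1c"))),
                     by = "donor_id") |>
    dplyr::mutate(age_scaled = as.numeric(scale(age)),
                  bmi_scaled = as.numeric(scale(bmi)))
  structure(list(counts = agg, design = design,
                 cells_per_sample = n_cells), class = "pseudobulk")
}

#' CPM log2 normalization
#'
#' `log2( (count + prior) / (colsum + 2 * prior) * 1e6 )`; the prior keeps
#' zero counts finite.
#'
#' @param counts genes-by-samples matrix (or a `pseudobulk`).
#' @param prior prior count (default 0.5).
#' @return matrix of log2 CPM values.
#' @export
cpm_log <- function(counts, prior = 0.5) {
  if (inherits(counts, "pseudobulk")) counts <- counts$counts
  tot <- colSums(counts)
  if (any(tot == 0)) stop("zero column sum", call. = FALSE)
  log2(sweep(counts + prior, 2, tot + 2 * prior, "/") * 1e6)
}

# --- negative binomial GLM machinery -------------------------------------

.nb_loglik <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta / (theta + mu)) +
        ifelse(y > 0, y * log(mu / (theta + mu)), 0))
}

.nb_irls <- function(y, X, offset, theta, tol = 1e-8, maxit = 100) {
  mu <- pmax(y, 0.5)
  eta <- log(mu) - offset
  beta <- qr.coef(qr(X), eta)
  beta[is.na(beta)] <- 0
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + mu / theta)
    z <- (eta - offset) + (y - mu) / mu
    beta_new <- qr.coef(qr(X * sqrt(w)), sqrt(w) * z)
    beta_new[is.na(beta_new)] <- 0
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  mu <- pmax(exp(drop(X %*% beta) + offset), 1e-10)
  list(coef = beta, mu = mu, loglik = .nb_loglik(y, mu, theta))
}

# profile MLE of the dispersion (1/theta) for one gene
.nb_mle_dispersion <- function(y, X, offset, lower = 1e-4, upper = 50) {
  prof <- function(log_disp) {
    .nb_irls(y, X, offset, theta = 1 / exp(log_disp))$loglik
  }
  opt <- stats::optimize(prof, c(log(lower), log(upper)), maximum = TRUE,
                         tol = 1e-4)
  exp(opt$maximum)
}

#' Fit per-gene NB-GLMs on pseudobulk counts
#'
#' Log-linear negative binomial regression with a log library-size offset.
#' Dispersion is estimated per gene by profile maximum likelihood and shrunk
#' toward the common (all-gene mean) dispersion by the weighted average
#' `w * common + (1 - w) * genewise` with `w = prior_df / (prior_df +
#' residual_df)`. Coefficients are then refit at the shrunk dispersion by
#' IRLS to tolerance 1e-8.
#'
#' @param pb a `pseudobulk` (restrict to one cell type first) or a
#'   genes-by-samples count matrix.
#' @param design data frame of per-sample covariates (required when `pb` is a
#'   bare matrix).
#' @param formula model formula over design columns; constant columns are
#'   dropped automatically.
#' @param prior_df prior degrees of freedom of the dispersion shrinkage
#'   (default 10).
#' @param offset optional per-sample log offset; defaults to the log column
#'   sums (library sizes).
#' @return list of class `nb_glm_fit`: `coef` (genes x coefficients),
#'   `dispersion` tibble, `design`, `X`, `offset`, `counts`, `formula`.
#' @export
fit_nb_glm <- function(pb, design = NULL,
                       formula = ~ state + chemistry + sex + ancestry +
                         age_scaled + bmi_scaled,
                       prior_df = 10, offset = NULL) {
  if (inherits(pb, "pseudobulk")) {
    design <- pb$design
    counts <- pb$counts
  } else counts <- as.matrix(pb)
  design <- as.data.frame(design)
  vars <- all.vars(formula)
  keep <- vars[vapply(vars, function(v)
    dplyr::n_distinct(design[[v]]) > 1, logical(1))]
  dropped <- setdiff(vars, keep)
  formula <- stats::reformulate(if (length(keep)) keep else "1")
  for (v in keep) if (is.character(design[[v]]) || is.factor(design[[v]]))
    design[[v]] <- droplevels(factor(design[[v]]))
  X <- stats::model.matrix(formula, design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (is.null(offset)) offset <- log(colSums(counts))
  stopifnot(length(offset) == ncol(counts))
  n <- ncol(counts); p <- ncol(X)
  resid_df <- n - p
  if (resid_df < 1) stop("no residual degrees of freedom", call. = FALSE)
  disp_gene <- vapply(seq_len(nrow(counts)), function(i)
    .nb_mle_dispersion(counts[i, ], X, offset), numeric(1))
  common <- mean(disp_gene)
  w <- prior_df / (prior_df + resid_df)
  disp_shrunk <- w * common + (1 - w) * disp_gene
  fits <- lapply(seq_len(nrow(counts)), function(i)
    .nb_irls(counts[i, ], X, offset, theta = 1 / disp_shrunk[i]))
  coef <- do.call(rbind, lapply(fits, `[[`, "coef"))
  dimnames(coef) <- list(rownames(counts), colnames(X))
  loglik <- vapply(fits, `[[`, numeric(1), "loglik")
  structure(list(coef = coef, loglik = loglik,
                 dispersion = tibble::tibble(
                   gene_id = rownames(counts), genewise = disp_gene,
                   common = common, shrunk = disp_shrunk),
                 design = design, X = X, offset = offset, counts = counts,
                 formula = formula, dropped_covariates = dropped),
            class = "nb_glm_fit")
}

#' @export
print.nb_glm_fit <- function(x, ...) {
  cat(sprintf("<nb_glm_fit> %d genes, %d samples, %s; common dispersion %.3f\n",
              nrow(x$counts), ncol(x$counts), deparse(x$formula),
              x$dispersion$common[1]))
  invisible(x)
}

#' Likelihood-ratio test of a contrast
#'
#' Tests a two-level contrast of a factor (e.g. `T2D` vs `ND` within `state`)
#' or a single model term by refitting, per gene, the reduced model in which
#' the two levels are merged (or the term removed) at the gene's shrunk
#' dispersion, and comparing likelihoods (1 df chi-square). `log2FC` is the
#' contrast coefficient divided by `ln 2`; BH FDR within the contrast.
#'
#' @param fit an `nb_glm_fit`.
#' @param factor_name name of the factor holding the contrast.
#' @param level1,level2 the two levels compared (`level1` minus `level2`).
#' @return tibble of class `de_result`: `gene_id`, `log2fc`, `stat`, `p`,
#'   `fdr`, with the contrast id as attribute `contrast`.
#' @export
test_contrast <- function(fit, factor_name, level1, level2) {
  design <- fit$design
  f <- design[[factor_name]]
  if (is.null(f)) stop("no such factor: ", factor_name, call. = FALSE)
  if (!all(c(level1, level2) %in% levels(factor(f))))
    stop("contrast references absent level", call. = FALSE)
  merged <- factor(ifelse(f %in% c(level1, level2), "MERGED",
                          as.character(f)))
  design_red <- design
  design_red[[factor_name]] <- merged
  red_formula <- fit$formula
  if (nlevels(droplevels(merged)) < 2) {
    # the factor had only the two contrasted levels: drop the term entirely
    others <- setdiff(all.vars(fit$formula), factor_name)
    red_formula <- stats::reformulate(if (length(others)) others else "1")
  }
  X_red <- stats::model.matrix(red_formula, design_red)
  res <- purrr::map_dfr(seq_len(nrow(fit$counts)), function(i) {
    theta <- 1 / fit$dispersion$shrunk[i]
    ll_full <- fit$loglik[i]
    ll_red <- .nb_irls(fit$counts[i, ], X_red, fit$offset, theta)$loglik
    stat <- max(2 * (ll_full - ll_red), 0)
    b <- fit$coef[i, ]
    coef_of <- function(lev) {
      nm <- paste0(factor_name, lev)
      if (nm %in% names(b)) b[[nm]] else 0     # reference level
    }
    tibble::tibble(gene_id = rownames(fit$counts)[i],
                   log2fc = (coef_of(level1) - coef_of(level2)) / log(2),
                   stat = stat,
                   p = stats::pchisq(stat, 1, lower.tail = FALSE))
  })
  res <- res |> dplyr::mutate(fdr = stats::p.adjust(p, "BH"))
  attr(res, "contrast") <- paste0(factor_name, ":", level1, "-vs-", level2)
  class(res) <- c("de_result", class(res))
  res
}

#' Call differentially expressed genes
#'
#' Splits a DE result into up- and down-regulated sets at the requested
#' absolute log2 fold-change and FDR thresholds (glycemic-state default:
#' `|log2FC| >= 0.585`, i.e. a 50% fold change, at `FDR <= 5%`).
#'
#' @param res a `de_result`.
#' @param lfc_min minimal |log2FC| (default 0.585).
#' @param fdr_max maximal FDR (default 0.05).
#' @return list `up`, `down` (character gene sets) and `table` (the filtered
#'   tibble).
#' @export
call_degs <- function(res, lfc_min = 0.585, fdr_max = 0.05) {
  hit <- res |> dplyr::filter(abs(log2fc) >= lfc_min, fdr <= fdr_max)
  list(up = hit$gene_id[hit$log2fc > 0], down = hit$gene_id[hit$log2fc < 0],
       table = hit)
}

#' Cell-type signature genes from one-vs-rest and pairwise results
#'
#' `preset = "methods"`: a gene is a signature of type z when upregulated
#' one-vs-rest at `log2FC >= 0.585`, `FDR <= 5%` and upregulated against
#' every other endocrine type pairwise at `|log2FC| >= 1`.
#' `preset = "results8fold"`: one-vs-rest `log2FC >= 3` at `FDR < 5%`.
#'
#' @param ovr named list (by cell type) of one-vs-rest `de_result`s.
#' @param pairwise named list (by cell type) of lists of pairwise
#'   `de_result`s against each other type (log2FC oriented as type minus
#'   other); ignored by the `results8fold` preset.
#' @param preset `"methods"` or `"results8fold"`.
#' @return named list of character signature gene sets per cell type.
#' @export
signature_genes <- function(ovr, pairwise = NULL,
                            preset = c("methods", "results8fold")) {
  preset <- match.arg(preset)
  purrr::imap(ovr, function(res, ty) {
    if (preset == "results8fold")
      return(res$gene_id[res$log2fc >= 3 & res$fdr < 0.05])
    base <- res$gene_id[res$log2fc >= 0.585 & res$fdr <= 0.05]
    if (is.null(pairwise) || is.null(pairwise[[ty]])) return(base)
    for (pw in pairwise[[ty]])
      base <- intersect(base, pw$gene_id[pw$log2fc >= 1])
    base
  })
}

#' @rdname tidy-isletpipe
#' @export
tidy.nb_glm_fit <- function(x, ...) {
  tibble::as_tibble(x$coef, rownames = "gene_id") |>
    tidyr::pivot_longer(-gene_id, names_to = "term", values_to = "estimate") |>
    dplyr::left_join(x$dispersion |> dplyr::select(gene_id,
                                                   dispersion = shrunk),
                     by = "gene_id")
}

#' @rdname tidy-isletpipe
#' @export
glance.nb_glm_fit <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$counts), n_samples = ncol(x$counts),
                 n_terms = ncol(x$X),
                 common_dispersion = x$dispersion$common[1])
}

#' Volcano plot of a differential expression result
#' @param object a `de_result`.
#' @param lfc_min,fdr_max thresholds drawn and used to colour calls.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.de_result <- function(object, lfc_min = 0.585, fdr_max = 0.05, ...) {
  df <- dplyr::mutate(object, call = dplyr::case_when(
    fdr <= fdr_max & log2fc >= lfc_min ~ "up",
    fdr <= fdr_max & log2fc <= -lfc_min ~ "down",
    TRUE ~ "ns"))
  ggplot2::ggplot(df, ggplot2::aes(log2fc, -log10(pmax(p, 1e-300)),
                                   colour = call)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "purple", down = "steelblue",
                                            ns = "grey70")) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = attr(object, "contrast")) +
    ggplot2::theme_minimal()
}
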
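#' Pipeline configuration
#'
#' Every stage parameter with its default, in one place. Defaults follow the
#' per-module documentation; override any subset by name.
#'
#' @param sim a [sim_config()] for the synthetic cohort stage.
#' @param ... overrides of the named defaults below.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), ...) {
  cfg <- list(
    sim = sim,
    empty_threshold = 10,
    demux_margin = 2, demux_min_calls = 3, demux_eps = 0.01,
    qc = qc_thresholds(),
    hvg_n = 2000, n_pcs = 30, snn_k = 20, resolution = 1,
    align_k = 10, align_iter = 10,
    annotate_z_min = 1,
    min_cells_pseudobulk = 10,
    de_lfc_min = 0.585, de_fdr_max = 0.05,
    wgcna_power = 12, wgcna_min_module = 20, wgcna_merge_cut = 0.25,
    wgcna_min_donors = 3,
    seed = 1L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

# greedily keep covariates that leave the model matrix full rank
.estimable_covariates <- function(design, candidates, base = character(0),
                                  min_resid_df = 1) {
  design <- as.data.frame(design) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.character), factor))
  kept <- character(0)
  for (cv in candidates) {
    trial <- stats::reformulate(c(base, kept, cv))
    X <- tryCatch(stats::model.matrix(trial, design),
                  error = function(e) NULL)
    if (!is.null(X) && qr(X)$rank == ncol(X) &&
        nrow(X) - ncol(X) >= min_resid_df)
      kept <- c(kept, cv)
  }
  kept
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes the stages in order: cohort simulation, soup estimation and
#' decontamination, genotype demultiplexing, preliminary QC, simulated
#' doublet scoring, integration with covariate alignment, graph clustering,
#' marker annotation, doublet-enrichment cluster removal, annotation-aware
#' pMT filtering, pseudobulk NB-GLM differential expression (beta cells,
#' T2D vs ND), co-expression modules on beta pseudobulk, evidence
#' prioritization and cohort composition statistics. Returns every stage
#' result plus a cell-accounting report whose removals reconcile exactly
#' with the kept count.
#'
#' @param cfg a [pipeline_config()].
#' @return list with stage outputs and `report`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  t0 <- Sys.time()
  log_stage <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

  log_stage("simulate: generating cohort")
  sc <- simulate_cohort(cfg$sim)
  mito <- intersect(.mito_genes, sc$raw[[1]]$gene_ids)

  log_stage("decontam: soup profiles and correction")
  corrected <- list(); soup_est <- list(); rho_est <- list()
  for (lib in names(sc$raw)) {
    soup <- estimate_soup_profile(sc$raw[[lib]], cfg$empty_threshold)
    filt <- sc$filtered[[lib]]
    nm <- lognormalize(filt)
    hvg <- select_hvg(nm, min(cfg$hvg_n, nrow(nm)))
    emb <- embed_pca(nm[hvg, ], n_pcs = min(cfg$n_pcs, ncol(nm) - 1))
    cl <- snn_cluster(emb, k = cfg$snn_k, resolution = cfg$resolution,
                      seed = cfg$seed)
    est <- estimate_contamination(filt, soup, cl$labels)
    corrected[[lib]] <- correct_counts(filt, soup, est)
    soup_est[[lib]] <- soup
    rho_est[[lib]] <- est
  }
  assessment <- assess_decontamination(sc$filtered, corrected)

  log_stage("demux: donor assignment")
  demux <- purrr::imap_dfr(sc$filtered, function(filt, lib) {
    donors_in <- sc$library_donors$donor_id[
      sc$library_donors$library_id == lib]
    pus <- sc$pileups[sc$pileups$library_id == lib, ]
    demux_library(filt, pus, sc$genotypes, donors_in,
                  doublet_margin = cfg$demux_margin,
                  min_calls = cfg$demux_min_calls, eps = cfg$demux_eps)
  })

  log_stage("qc: metrics, preliminary filter, doublet scores")
  cells <- compute_cell_metrics_multi(sc$filtered, mito) |>
    preliminary_filter(cfg$qc) |>
    dplyr::left_join(demux |>
                       dplyr::select(library_id, barcode_id, best_type,
                                     donor_id = donor1),
                     by = c("library_id", "barcode_id")) |>
    dplyr::mutate(
      filtered = filtered | best_type == "doublet",
      reason = dplyr::if_else(best_type == "doublet",
                              ifelse(is.na(reason), "demux_doublet",
                                     paste(reason, "demux_doublet",
                                           sep = ",")),
                              reason),
      donor_id = dplyr::if_else(best_type == "singlet", donor_id,
                                NA_character_))
  scores <- purrr::imap_dfr(sc$filtered, function(filt, lib) {
    keep_bc <- cells$barcode_id[cells$library_id == lib & !cells$filtered]
    nm <- lognormalize(counts_matrix(
      filt$values[, keep_bc, drop = FALSE], filt$gene_ids, keep_bc, lib))
    simulated_doublet_scores(nm, cfg$qc, seed = cfg$seed) |>
      dplyr::mutate(library_id = lib)
  })
  cells <- cells |>
    dplyr::left_join(scores |>
                       dplyr::select(library_id, barcode_id,
                                     doublet_score = score,
                                     consensus_doublet = consensus),
                     by = c("library_id", "barcode_id")) |>
    dplyr::mutate(consensus_doublet =
                    dplyr::coalesce(consensus_doublet, FALSE))

  log_stage("integrate: PCA, covariate alignment, clustering")
  keep <- cells |> dplyr::filter(!filtered)
  merged <- do.call(cbind, purrr::imap(sc$filtered, function(filt, lib) {
    bc <- keep$barcode_id[keep$library_id == lib]
    m <- filt$values[, bc, drop = FALSE]
    colnames(m) <- paste(lib, bc, sep = "|")
    m
  }))
  nm_all <- lognormalize(merged)
  hvg <- select_hvg(nm_all, min(cfg$hvg_n, nrow(nm_all)))
  emb <- embed_pca(nm_all[hvg, ], n_pcs = min(cfg$n_pcs, ncol(nm_all) - 1))
  keyed <- paste(keep$library_id, keep$barcode_id, sep = "|")
  covar <- keep |>
    dplyr::left_join(sc$donors |>
                       dplyr::select(donor_id, sex, ancestry, chemistry),
                     by = "donor_id") |>
    dplyr::select(sex, ancestry, chemistry) |>
    dplyr::mutate(dplyr::across(dplyr::everything(),
                                ~ dplyr::coalesce(.x, "unknown")))
  emb <- covariate_align(emb, covar, k = cfg$align_k,
                         n_iter = cfg$align_iter, seed = cfg$seed)
  clustering <- snn_cluster(emb, k = cfg$snn_k,
                            resolution = cfg$resolution, seed = cfg$seed)

  log_stage("annotate: marker z-scores")
  annotation <- annotate_clusters(clustering, nm_all,
                                  panel = marker_panel()[
                                    marker_panel() %in% rownames(nm_all)],
                                  z_min = cfg$annotate_z_min)
  keep$cluster <- unname(clustering$labels[keyed])
  keep <- keep |>
    dplyr::left_join(annotation |> dplyr::select(cluster, cell_type),
                     by = "cluster")

  log_stage("doublet enrichment: cluster-level statistic")
  enr <- doublet_enrichment_test(keep$cluster, keep$consensus_doublet)
  coex <- hormone_coexpression_flags(nm_all, keep$cluster)
  keep <- remove_enriched_clusters(keep, keep$cluster, enr, coex,
                                   keep$consensus_doublet)
  keep <- annotation_aware_filter(keep, cfg$qc)
  final <- keep |> dplyr::filter(!filtered)

  cells_post <- cells |>
    dplyr::rows_update(keep |> dplyr::select(library_id, barcode_id,
                                             filtered, reason),
                       by = c("library_id", "barcode_id"))

  log_stage("pseudobulk DE: beta cells, T2D vs ND")
  pb <- aggregate_pseudobulk(final, sc$filtered, sc$donors,
                             min_cells = cfg$min_cells_pseudobulk)
  beta_idx <- pb$design$cell_type == "beta"
  de <- NULL
  if (sum(beta_idx) >= 4 &&
      all(c("ND", "T2D") %in% pb$design$state[beta_idx])) {
    pb_beta <- pb$counts[, beta_idx, drop = FALSE]
    keep_g <- rowSums(pb_beta > 0) >= 2
    des_beta <- pb$design[beta_idx, ]
    # keep nuisance covariates only while the design stays estimable
    kept_cov <- .estimable_covariates(
      des_beta, c("chemistry", "sex", "ancestry", "age_scaled",
                  "bmi_scaled"), base = "state", min_resid_df = 2)
    fit <- suppressWarnings(
      fit_nb_glm(pb_beta[keep_g, ], des_beta,
                 formula = stats::reformulate(c("state", kept_cov))))
    de <- test_contrast(fit, "state", "T2D", "ND")
  }
  degs <- if (!is.null(de)) call_degs(de, cfg$de_lfc_min, cfg$de_fdr_max)
  else NULL

  log_stage("co-expression: beta pseudobulk modules")
  modules <- NULL
  if (sum(beta_idx) > cfg$wgcna_min_donors) {
    expr <- t(cpm_log(pb$counts[
      filter_expressed_genes(pb$counts[, beta_idx, drop = FALSE],
                             cfg$wgcna_min_donors),
      beta_idx, drop = FALSE]))
    resid_cov <- .estimable_covariates(
      pb$design[beta_idx, ], c("sex", "ancestry", "chemistry",
                               "age_scaled", "bmi_scaled"),
      min_resid_df = 2)
    resid <- if (length(resid_cov))
      residualize_covariates(expr,
                             pb$design[beta_idx, resid_cov, drop = FALSE])
    else expr
    resid <- resid[, apply(resid, 2, stats::sd) > 0, drop = FALSE]
    adj <- signed_adjacency(resid, cfg$wgcna_power)
    tom <- tom_similarity(adj)
    modules <- detect_modules(1 - tom, resid,
                              min_module_size = cfg$wgcna_min_module,
                              merge_cut_height = cfg$wgcna_merge_cut)
  }

  log_stage("prioritize: evidence integration")
  deg_table <- sc$evidence$deg
  variants <- expand_ld_proxies(sc$evidence$gwas, sc$evidence$ld)
  eqtls <- filter_eqtls(sc$evidence$eqtl)
  calls <- classify_concordance(variants, eqtls, deg_table)
  candidates <- integrate_evidence(calls, sc$evidence$protein,
                                   sc$evidence$mouse)

  log_stage("cohort stats: composition and similarity")
  comp <- composition_table(final, sc$donors)
  comp_tests <- composition_tests(comp)
  comp_trait <- composition_trait_correlation(comp)
  sim_attr <- state_attribute_vectors(sc$donors)
  sims <- utils::combn(rownames(sim_attr), 2)
  similarity <- purrr::map_dfr(seq_len(ncol(sims)), function(i)
    tibble::tibble(state1 = sims[1, i], state2 = sims[2, i],
                   similarity = state_similarity(sim_attr[sims[1, i], ],
                                                 sim_attr[sims[2, i], ])))

  # cell accounting: every non-kept droplet carries >= 1 reason
  removed <- cells_post |> dplyr::filter(filtered)
  reasons <- removed |>
    tidyr::separate_rows(reason, sep = ",") |>
    dplyr::count(reason)
  report <- list(
    n_droplets = nrow(cells_post),
    n_kept = sum(!cells_post$filtered),
    n_removed = nrow(removed),
    removal_reasons = reasons,
    audit_ok = nrow(cells_post) == sum(!cells_post$filtered) + nrow(removed) &&
      all(!is.na(removed$reason)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    seed = cfg$seed)

  list(cohort = sc, soup = soup_est, rho = rho_est, corrected = corrected,
       assessment = assessment, demux = demux, cells = cells_post,
       clustering = clustering, annotation = annotation,
       enrichment = enr, final_cells = final, pseudobulk = pb, de = de,
       degs = degs, modules = modules, candidates = candidates,
       composition = comp, composition_tests = comp_tests,
       composition_trait = comp_trait, state_similarity = similarity,
       report = report)
}
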
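test_that("the generator is deterministic under a fixed configuration", {
  cfg <- small_sim_config(seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$donors, b$donors)
  expect_identical(a$truth, b$truth)
  expect_identical(a$pileups, b$pileups)
  expect_equal(as.matrix(a$raw[[1]]$values), as.matrix(b$raw[[1]]$values))
})

test_that("donor metadata follows the per-state HbA1c means", {
  cfg <- sim_config(seed = 3, n_donors = c(ND = 17L, PD = 14L, T2D = 17L))
  d <- simulate_donor_metadata(cfg)
  expect_equal(mean(d$hba1c[d$state == "T2D"]), 7.6, tolerance = 0.3 / 7.6)
  expect_lt(abs(mean(d$hba1c[d$state == "ND"]) - 5.2), 0.3)

  single <- simulate_donor_metadata(sim_config(n_donors = c(ND = 1L, PD = 0L,
                                                            T2D = 0L)))
  expect_equal(nrow(single), 1)
  expect_equal(as.character(single$state), "ND")
})

test_that("planted effects drive beta-cell composition and expression", {
  sc <- small_cohort()
  # realized T2D beta fraction below ND (direction check)
  frac <- sc$truth |>
    dplyr::filter(!empty, !doublet) |>
    dplyr::left_join(sc$donors, by = "donor_id") |>
    dplyr::filter(cell_type %in% c("beta", "alpha", "delta", "gamma")) |>
    dplyr::group_by(donor_id, state) |>
    dplyr::summarise(beta = mean(cell_type == "beta"), .groups = "drop")
  expect_lt(mean(frac$beta[frac$state == "T2D"]),
            mean(frac$beta[frac$state == "ND"]))

  # no planted fold change: beta-cell means match across states
  cfg0 <- small_sim_config(seed = 5)
  cfg0$n_planted_deg <- 0L
  cfg0$n_evidence <- c(concordant = 0L, discordant = 0L, mixed = 0L)
  sc0 <- simulate_cohort(cfg0)
  nm <- do.call(cbind, lapply(sc0$filtered, function(m) as.matrix(m$values)))
  truth <- sc0$truth |> dplyr::filter(!empty)
  truth <- truth[match(colnames(nm), truth$barcode_id), ]
  beta_nd <- truth$cell_type == "beta" & !truth$doublet &
    truth$donor_id %in% sc0$donors$donor_id[sc0$donors$state == "ND"]
  beta_t2d <- truth$cell_type == "beta" & !truth$doublet &
    truth$donor_id %in% sc0$donors$donor_id[sc0$donors$state == "T2D"]
  rel_nd <- rowSums(nm[, beta_nd]) / sum(nm[, beta_nd])
  rel_t2d <- rowSums(nm[, beta_t2d]) / sum(nm[, beta_t2d])
  top <- order(-rel_nd)[1:50]
  expect_equal(rel_t2d[top], rel_nd[top], tolerance = 0.15)
})

test_that("NB counts approach the Poisson limit as dispersion vanishes", {
  set.seed(1)
  mu <- 5
  x <- rnbinom(1e4, size = 1 / 1e-8, mu = mu)
  expect_equal(var(x) / mean(x), 1, tolerance = 0.05)
})

test_that("ambient overlay conserves totals and respects rho limits", {
  cfg <- small_sim_config(seed = 13)
  donors <- simulate_donor_metadata(cfg)
  sim <- simulate_true_counts(cfg, donors)

  # rho = 0: raw equals true counts exactly
  cfg0 <- cfg; cfg0$rho_shape1 <- 1e-8; cfg0$rho_shape2 <- 1e4
  cfg0$n_empty_droplets <- 10L
  amb0 <- apply_ambient_and_empties(sim, cfg0)
  lib <- names(sim$counts)[1]
  cells <- sim$counts[[lib]]$barcode_ids
  expect_equal(as.matrix(amb0$counts[[lib]]$values[, cells]),
               as.matrix(sim$counts[[lib]]$values))

  # rho = 1: pooled cell counts match the soup profile within multinomial error
  cfg1 <- cfg; cfg1$rho_shape1 <- 1e6; cfg1$rho_shape2 <- 1
  cfg1$n_empty_droplets <- 10L
  amb1 <- apply_ambient_and_empties(sim, cfg1)
  pooled <- Matrix::rowSums(amb1$counts[[lib]]$values[, cells])
  pooled <- pooled / sum(pooled)
  expect_lt(0.5 * sum(abs(pooled - amb1$soup[[lib]])), 0.05)

  # defaults: totals conserved per cell, truth covers every droplet
  amb <- apply_ambient_and_empties(sim, cfg)
  expect_equal(unname(Matrix::colSums(amb$counts[[lib]]$values[, cells])),
               unname(Matrix::colSums(sim$counts[[lib]]$values)))
  expect_setequal(amb$truth$barcode_id[amb$truth$library_id == lib],
                  amb$counts[[lib]]$barcode_ids)

  # top soup genes are the hormone-dominated most-expressed genes
  top_soup <- names(sort(amb$soup[[lib]], decreasing = TRUE))[1:4]
  expect_true(all(c("INS", "GCG") %in% top_soup))
})

test_that("doublet injection is additive and conserves merged UMIs", {
  cfg <- small_sim_config(seed = 17)
  cfg$n_empty_droplets <- 10L
  donors <- simulate_donor_metadata(cfg)
  sim <- apply_ambient_and_empties(simulate_true_counts(cfg, donors), cfg)
  tot_before <- sum(vapply(sim$counts, function(m) sum(m$values), numeric(1)))

  out <- inject_doublets(sim, cfg)
  tot_after <- sum(vapply(out$counts, function(m) sum(m$values), numeric(1)))
  expect_equal(tot_after, tot_before)  # conservation of merged UMIs

  dbl <- out$truth |> dplyr::filter(doublet)
  n_cells <- sum(!sim$truth$empty)
  expect_gt(nrow(dbl), 0)
  expect_lt(abs(nrow(dbl) - 0.1 * n_cells), 4 * sqrt(0.1 * 0.9 * n_cells))

  cfg0 <- cfg; cfg0$doublet_rate <- 0
  out0 <- inject_doublets(sim, cfg0)
  expect_equal(as.matrix(out0$counts[[1]]$values),
               as.matrix(sim$counts[[1]]$values))
  expect_error(inject_doublets(sim, within(cfg, doublet_rate <- 1)))
})

test_that("genotype pileups follow the stated base-call error model", {
  cfg <- small_sim_config(seed = 19)
  cfg$reads_per_variant <- 3; cfg$n_variants <- 200L
  sc <- simulate_cohort(cfg)
  gmat <- tidyr::pivot_wider(sc$genotypes, names_from = donor_id,
                             values_from = dosage)
  # restrict to homozygous variants of singlets: mismatches are pure error
  sing <- sc$truth |> dplyr::filter(!empty, !doublet)
  pu <- sc$pileups |>
    dplyr::inner_join(sing |> dplyr::select(barcode_id, donor_id),
                      by = "barcode_id") |>
    dplyr::left_join(sc$genotypes, by = c("variant_id", "donor_id")) |>
    dplyr::filter(dosage %in% c(0, 2))
  n_calls <- sum(pu$n_ref + pu$n_alt)
  mism <- sum(ifelse(pu$dosage == 0, pu$n_alt, pu$n_ref))
  expect_gt(n_calls, 1e5)
  expect_equal(mism / n_calls, cfg$base_error, tolerance = 0.15)
})

test_that("planted evidence constructions match their intended classes", {
  sc <- small_cohort()
  ev <- sc$evidence
  expect_true(all(grepl("^[+-]{4}$", ev$eqtl$cohort_directions)))
  mixed_genes <- ev$truth$gene[ev$truth$class == "mixed"]
  for (g in mixed_genes) {
    zs <- ev$eqtl$z[ev$eqtl$gene == g]
    expect_equal(length(zs), 2)
    expect_lt(prod(sign(zs)), 0)   # opposite signs
  }
  # every proxy row is at r2 >= 0.80 or marks an independent signal pair
  expect_true(all(ev$ld$r2 >= 0.8 | ev$ld$r2 < 0.5))
})
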
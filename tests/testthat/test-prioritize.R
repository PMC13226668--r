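gwas1 <- tibble::tibble(variant_id = "rs1", risk_allele = "A",
                        other_allele = "G", odds_ratio = 1.07, p = 5e-9,
                        locus_id = "L1")

test_that("LD expansion honours the r2 boundary and keeps orientation provenance", {
  ld <- tibble::tibble(variant_id1 = "rs1", variant_id2 = c("rs2", "rs3"),
                       r2 = c(0.80, 0.79), aligned_allele = c("T", "C"))
  out <- expand_ld_proxies(gwas1, ld)
  expect_true("rs2" %in% out$variant_id)    # r2 = 0.80 included
  expect_false("rs3" %in% out$variant_id)   # r2 = 0.79 excluded
  expect_equal(out$risk_allele[out$variant_id == "rs2"], "T")
  # empty LD table: identity
  expect_equal(expand_ld_proxies(gwas1, NULL)$variant_id, "rs1")
})

test_that("eQTL filtering is strict in p and direction-consistent", {
  rec <- tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v4"),
    effect_allele = "A", gene = "G1", z = c(2, -2, 2, 2),
    p = c(0.04, 0.04, 0.05, 0.01),
    cohort_directions = c("----", "----", "++++", "+++-"))
  out <- filter_eqtls(rec)
  expect_equal(out$variant_id, c("v1", "v2"))  # v3 fails strict p, v4 mixed
  expect_error(filter_eqtls(dplyr::mutate(rec, cohort_directions = "++")),
               "malformed")
})

test_that("the printed worked examples classify as stated", {
  # downregulated DEG (log2FC = -1.36) with oriented eQTL z = -2.02
  sgk2_var <- tibble::tibble(variant_id = "rs67897819", risk_allele = "A",
                             other_allele = "G", odds_ratio = 1.07,
                             p = 5e-9, locus_id = "hnf4a") |>
    expand_ld_proxies(NULL)
  sgk2_eqtl <- tibble::tibble(variant_id = "rs67897819", effect_allele = "A",
                              gene = "SGK2", z = -2.02, p = 0.04,
                              cohort_directions = "----")
  call1 <- classify_concordance(sgk2_var, sgk2_eqtl,
                                tibble::tibble(gene = "SGK2",
                                               log2fc = -1.36))
  expect_equal(call1$class, "concordant")

  # two independent signals with opposite oriented z, log2FC = -0.72
  pit_var <- tibble::tibble(
    variant_id = c("rs28413626", "rs1260294"), risk_allele = c("A", "T"),
    other_allele = c("G", "C"), odds_ratio = c(1.03, 1.04), p = 5e-9,
    locus_id = c("sig1", "sig2")) |>
    expand_ld_proxies(tibble::tibble(variant_id1 = "rs28413626",
                                     variant_id2 = "rs1260294", r2 = 0.28,
                                     aligned_allele = NA_character_))
  pit_eqtl <- tibble::tibble(
    variant_id = c("rs28413626", "rs1260294"),
    effect_allele = c("A", "T"), gene = "PITPNM2", z = c(2.1, -2.18),
    p = 0.01, cohort_directions = c("++++", "----"))
  call2 <- classify_concordance(pit_var, pit_eqtl,
                                tibble::tibble(gene = "PITPNM2",
                                               log2fc = -0.72))
  expect_equal(call2$class, "mixed")
  expect_equal(call2$n_signals, 2)
})

test_that("orientation involution and row order never change a call", {
  eqtl <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
                         gene = "G1", z = -2.5, p = 0.01,
                         cohort_directions = "----")
  degs <- tibble::tibble(gene = "G1", log2fc = -1)
  vars <- expand_ld_proxies(gwas1, NULL)
  base <- classify_concordance(vars, eqtl, degs)
  flipped <- eqtl |> dplyr::mutate(effect_allele = "G", z = -z)
  expect_equal(classify_concordance(vars, flipped, degs)$class, base$class)

  # z = 0 is uninformative
  z0 <- eqtl |> dplyr::mutate(z = 0)
  expect_equal(nrow(classify_concordance(vars, z0, degs)), 0)

  # permutation invariance on a larger random table
  sc <- small_cohort()
  ev <- sc$evidence
  v <- expand_ld_proxies(ev$gwas, ev$ld)
  e <- filter_eqtls(ev$eqtl)
  a <- classify_concordance(v, e, ev$deg)
  set.seed(1)
  b <- classify_concordance(v[sample(nrow(v)), ], e[sample(nrow(e)), ],
                            ev$deg[sample(nrow(ev$deg)), ])
  expect_equal(dplyr::arrange(tibble::as_tibble(a), gene),
               dplyr::arrange(tibble::as_tibble(b), gene))
})

test_that("planted concordance classes are recovered exactly", {
  sc <- small_cohort()
  ev <- sc$evidence
  calls <- classify_concordance(expand_ld_proxies(ev$gwas, ev$ld),
                                filter_eqtls(ev$eqtl), ev$deg)
  merged <- dplyr::inner_join(calls, ev$truth, by = "gene",
                              suffix = c("", "_true"))
  expect_equal(nrow(merged), nrow(ev$truth))
  expect_equal(merged$class, merged$class_true)
})

test_that("orthogonal evidence sets flags and candidacy as specified", {
  calls <- tibble::tibble(
    gene = c("down_gene", "up_gene", "lonely"),
    class = c("discordant", "discordant", "concordant"),
    n_signals = 1, deg_log2fc = c(-1.2, 0.9, -0.5),
    supporting_variants = "rsX")
  class(calls) <- c("concordance_calls", class(calls))
  protein <- tibble::tibble(gene = "down_gene", log2fc_protein = -0.8,
                            p = 0.01)
  mouse <- tibble::tibble(gene = c("down_gene", "up_gene"),
                          phenotype = "glucose_tolerance",
                          direction = c("impaired", "improved"))
  out <- integrate_evidence(calls, protein, mouse)
  dg <- out[out$gene == "down_gene", ]
  expect_true(dg$protein_direction_match && dg$mouse_ko_direction_match)
  expect_true(dg$candidate)
  expect_true(out$mouse_ko_direction_match[out$gene == "up_gene"])
  lonely <- out[out$gene == "lonely", ]
  expect_false(lonely$protein_direction_match ||
                 lonely$mouse_ko_direction_match)
  expect_true(lonely$candidate)   # concordant class alone suffices
})
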
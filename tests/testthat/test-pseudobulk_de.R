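donors2 <- tibble::tibble(
  donor_id = c("D1", "D2"), state = factor(c("ND", "T2D")),
  chemistry = c("V2", "V3"), sex = c("F", "M"), ancestry = "EUR",
  age = c(50, 60), bmi = c(25, 30), hba1c = c(5.2, 7.5))

test_that("pseudobulk aggregation is an exact, order-invariant column sum", {
  m <- tiny_counts(cbind(c(1, 2), c(3, 4), c(7, 1)), lib = "L1")
  cells <- tibble::tibble(
    library_id = "L1", barcode_id = c("c1", "c2", "c3"),
    donor_id = c("D1", "D1", "D2"), cell_type = c("beta", "beta", "alpha"))
  pb <- suppressWarnings(aggregate_pseudobulk(cells, list(L1 = m), donors2,
                                              min_cells = 1))
  expect_equal(unname(pb$counts[, "D1.beta"]), c(4, 6))
  # no (donor, delta) column when the donor has no delta cells
  expect_false("D1.delta" %in% colnames(pb$counts))
  # permuting cell order changes nothing
  pb2 <- suppressWarnings(aggregate_pseudobulk(cells[c(3, 1, 2), ],
                                               list(L1 = m), donors2,
                                               min_cells = 1))
  expect_equal(pb$counts, pb2$counts[rownames(pb$counts), colnames(pb$counts)])
  # exact reconciliation with single-cell totals
  expect_equal(sum(pb$counts), sum(m$values))
})

test_that("CPM normalization matches its formula and invariances", {
  counts <- cbind(s1 = c(5, 5), s2 = c(2, 8))
  rownames(counts) <- c("a", "b")
  expect_equal(unname(cpm_log(counts, prior = 0)[, 1]),
               rep(log2(5e5), 2))
  expect_equal(cpm_log(counts * 2, prior = 0)[, 1],
               cpm_log(counts, prior = 0)[, 1])
  withzero <- cbind(s1 = c(0, 10))
  expect_true(all(is.finite(cpm_log(withzero, prior = 0.5))))
  expect_error(cpm_log(cbind(c(0, 0))), "zero column")
})

test_that("the NB-GLM agrees with a direct likelihood-maximization oracle", {
  set.seed(14)
  n <- 16
  design <- tibble::tibble(state = factor(rep(c("ND", "T2D"), each = n / 2)))
  mu <- exp(3 + 0.8 * (design$state == "T2D"))
  counts <- matrix(rnbinom(3 * n, size = 5, mu = rep(mu, each = 3)), 3,
                   dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:n)))
  fit <- fit_nb_glm(counts, design, formula = ~ state)
  X <- fit$X
  off <- fit$offset
  for (i in 1:3) {
    theta <- 1 / fit$dispersion$shrunk[i]
    nll <- function(b) -isletpipe:::.nb_loglik(
      counts[i, ], pmax(exp(drop(X %*% b) + off), 1e-10), theta)
    oracle <- optim(c(0, 0), nll, method = "BFGS",
                    control = list(reltol = 1e-14, maxit = 2000))
    expect_equal(unname(fit$coef[i, ]), oracle$par, tolerance = 1e-5)
  }
})

test_that("dispersion estimation shrinks and detects the Poisson limit", {
  set.seed(15)
  n <- 30
  design <- tibble::tibble(state = factor(rep(c("ND", "T2D"), each = n / 2)))
  counts <- matrix(rpois(50 * n, 40), 50,
                   dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:n)))
  fit <- fit_nb_glm(counts, design, formula = ~ state)
  expect_lt(median(fit$dispersion$shrunk), 0.02)
})

test_that("coefficients recover planted effects with small bias", {
  set.seed(16)
  n <- 60
  design <- tibble::tibble(state = factor(rep(c("ND", "T2D"), each = n / 2)))
  beta_true <- 0.7
  libsize <- rlnorm(n, log(1e4), 0.2)
  mu <- outer(rep(4e-3, 200), libsize) *
    2^outer(rep(1, 200), beta_true / log(2) * (design$state == "T2D"))
  counts <- matrix(rnbinom(200 * n, size = 8, mu = mu), 200,
                   dimnames = list(sprintf("g%d", 1:200),
                                   sprintf("s%d", 1:n)))
  # known true library sizes as offsets isolate estimation bias
  fit <- fit_nb_glm(counts, design, formula = ~ state,
                    offset = log(libsize))
  expect_lt(abs(mean(fit$coef[, "stateT2D"]) - beta_true), 0.05)
})

test_that("contrasts are antisymmetric and rank-deficiency is reported", {
  set.seed(17)
  n <- 18
  design <- tibble::tibble(
    state = factor(rep(c("ND", "PD", "T2D"), each = n / 3)),
    sex = rep(c("F", "M"), 9))
  counts <- matrix(rnbinom(20 * n, size = 5, mu = 50), 20,
                   dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:n)))
  fit <- fit_nb_glm(counts, design, formula = ~ state + sex)
  ab <- test_contrast(fit, "state", "T2D", "ND")
  ba <- test_contrast(fit, "state", "ND", "T2D")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p, ba$p)
  expect_error(test_contrast(fit, "state", "T2D", "XX"), "absent level")

  design_bad <- design |> dplyr::mutate(dup = as.character(state))
  expect_error(fit_nb_glm(counts, design_bad, formula = ~ state + dup),
               "aliased")
})

test_that("DEG calling respects both thresholds at their boundaries", {
  res <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                        log2fc = c(0.60, 0.58, -1.0, 1.0),
                        stat = 1, p = 0.01,
                        fdr = c(0.04, 0.01, 0.051, 0.05))
  out <- call_degs(res)
  expect_equal(out$up, c("a", "d"))
  expect_equal(out$down, character(0))  # c fails FDR, b fails log2FC
})

test_that("signature presets apply the uniqueness and 8-fold rules", {
  ovr <- list(beta = tibble::tibble(
    gene_id = c("m1", "m2", "m3"), log2fc = c(3.0, 2.0, 0.7),
    stat = 1, p = 1e-4, fdr = c(1e-4, 1e-4, 1e-3)))
  pw <- list(beta = list(
    alpha = tibble::tibble(gene_id = c("m1", "m2", "m3"),
                           log2fc = c(2, 0.5, 2)),
    delta = tibble::tibble(gene_id = c("m1", "m2", "m3"),
                           log2fc = c(3, 2, 2))))
  sig <- signature_genes(ovr, pw, preset = "methods")
  expect_equal(sig$beta, c("m1", "m3"))   # m2 fails one pairwise comparison
  sig8 <- signature_genes(ovr, preset = "results8fold")
  expect_equal(sig8$beta, "m1")           # log2FC = 3.0 included (>=)
})

test_that("BH adjustment equals the direct definition", {
  set.seed(18)
  p <- runif(200)^2
  expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
})

test_that("tidiers summarize NB fits", {
  set.seed(19)
  design <- tibble::tibble(state = factor(rep(c("ND", "T2D"), each = 5)))
  counts <- matrix(rnbinom(30, size = 5, mu = 30), 3,
                   dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:10)))
  fit <- fit_nb_glm(counts, design, formula = ~ state)
  td <- tidy(fit)
  expect_true(all(c("gene_id", "term", "estimate") %in% names(td)))
  expect_equal(nrow(glance(fit)), 1)
})
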
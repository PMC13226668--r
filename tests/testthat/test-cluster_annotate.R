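test_that("log-normalization matches its formula and compositional invariance", {
  m <- tiny_counts(cbind(c(5, 5), c(0, 2)), genes = c("gA", "gB"))
  nm <- lognormalize(m)
  expect_equal(nm["gA", 1], log(1 + 10000 * 5 / 10))
  expect_equal(nm["gA", 2], 0)
  # doubling a cell's counts leaves its normalized vector unchanged
  m2 <- tiny_counts(cbind(c(10, 10), c(0, 4)), genes = c("gA", "gB"))
  expect_equal(lognormalize(m2), lognormalize(m))
  # zero-total cell maps to zeros
  z <- tiny_counts(cbind(c(0, 0)), genes = c("gA", "gB"))
  expect_equal(unname(lognormalize(z)[, 1]), c(0, 0))
})

test_that("variable-gene selection recovers planted variability", {
  set.seed(4)
  n_cells <- 300
  means <- rlnorm(400, log(2), 0.8)
  nm <- matrix(rnorm(400 * n_cells, mean = means, sd = 0.4), 400)
  nm <- pmax(nm, 0)
  rownames(nm) <- sprintf("g%03d", 1:400)
  # plant 20 genes with strong bimodal variation
  hv <- sample(400, 20)
  nm[hv, ] <- nm[hv, ] + rep(rbinom(n_cells, 1, 0.5) * 3, each = 20)
  picked <- select_hvg(nm, 40)
  expect_gte(mean(rownames(nm)[hv] %in% picked), 0.95)

  # constant genes score zero: never selected while varying genes exist
  nm2 <- nm
  nm2[1:10, ] <- 3      # constant rows on the normalized scale
  rownames(nm2)[1:10] <- sprintf("const%02d", 1:10)
  expect_false(any(sprintf("const%02d", 1:10) %in% select_hvg(nm2, 390)))
  # n equal to gene count returns every gene
  expect_setequal(select_hvg(nm2, nrow(nm2)), rownames(nm2))
  expect_error(select_hvg(nm, 1000), "exceeds")
})

test_that("PCA embedding is complete, ordered and sign-fixed", {
  set.seed(5)
  # rank-1 data: PC1 explains ~100%
  u <- rnorm(80); v <- abs(rnorm(20))
  line <- outer(v, u) + matrix(rnorm(1600, sd = 1e-3), 20)
  dimnames(line) <- list(sprintf("g%d", 1:20), sprintf("c%d", 1:80))
  emb <- embed_pca(line, n_pcs = 5)
  expect_gt(emb$explained[1], 0.99)
  expect_true(all(diff(emb$sdev) <= 1e-8))

  # full reconstruction of the scaled input
  X <- scale(t(line))
  emb_full <- embed_pca(line, n_pcs = 20)
  rec <- emb_full$x %*% t(emb_full$rotation)
  expect_equal(unname(rec), unname(X[, ]), tolerance = 1e-8)
})

test_that("covariate alignment removes planted offsets and respects no-ops", {
  set.seed(6)
  X <- matrix(rnorm(400 * 5), 400)
  rownames(X) <- sprintf("c%d", 1:400)
  e <- structure(list(x = X), class = "embedding")
  chem <- rep(c("V2", "V3"), each = 200)

  # identical covariate for all cells: no-op
  same <- covariate_align(e, data.frame(chem = rep("V3", 400)))
  expect_equal(same$x, X)

  # planted offset on PC1 for V2
  X_off <- X
  X_off[chem == "V2", 1] <- X_off[chem == "V2", 1] + 4
  e_off <- structure(list(x = X_off), class = "embedding")
  before <- abs(mean(X_off[chem == "V2", 1]) - mean(X_off[chem == "V3", 1]))
  out <- covariate_align(e_off, data.frame(chem = chem), seed = 2)
  after <- sqrt(sum((colMeans(out$x[chem == "V2", ]) -
                       colMeans(out$x[chem == "V3", ]))^2))
  expect_lt(after, 0.1 * before)

  # determinism
  out2 <- covariate_align(e_off, data.frame(chem = chem), seed = 2)
  expect_identical(out$x, out2$x)
})

test_that("graph clustering separates blobs and respects limits", {
  set.seed(7)
  blob <- rbind(matrix(rnorm(150 * 8), 150),
                matrix(rnorm(150 * 8, mean = 7), 150))
  rownames(blob) <- sprintf("c%d", 1:300)
  truth <- rep(1:2, each = 150)
  cl <- snn_cluster(blob, k = 30, resolution = 1, seed = 1)
  expect_equal(adjusted_rand_index(cl$labels, truth), 1)
  expect_equal(sort(unique(cl$labels)), 0:1)

  # resolution -> 0 on a connected dataset: single cluster
  one <- matrix(rnorm(200 * 5), 200)
  rownames(one) <- sprintf("c%d", 1:200)
  cl0 <- snn_cluster(one, k = 20, resolution = 1e-4, seed = 1)
  expect_equal(length(unique(cl0$labels)), 1)

  expect_error(snn_cluster(blob[1:10, ], k = 20), "below")

  # duplicated data: each cell and its twin share a cluster
  dup <- rbind(blob, blob)
  rownames(dup) <- sprintf("c%d", 1:600)
  cld <- snn_cluster(dup, k = 30, resolution = 1, seed = 1)
  expect_equal(mean(cld$labels[1:300] == cld$labels[301:600]), 1)
})

test_that("marker annotation assigns planted types and flags multi-hormone", {
  set.seed(8)
  genes <- c("INS", "SST", "GCG", "PPY", sprintf("g%d", 1:16))
  mk <- function(hot, n) {
    m <- matrix(rpois(20 * n, 2), 20, dimnames = list(genes, NULL))
    m[hot, ] <- m[hot, ] + 50
    m
  }
  counts <- cbind(mk("INS", 40), mk("GCG", 40), mk("SST", 40),
                  mk("PPY", 40), mk(c("INS", "SST"), 40))
  colnames(counts) <- sprintf("c%d", seq_len(ncol(counts)))
  nm <- lognormalize(tiny_counts(counts, genes = genes))
  labels <- rep(0:4, each = 40)
  ann <- annotate_clusters(labels, nm, z_min = 0.9,
                           panel = marker_panel()[c("beta", "alpha",
                                                    "delta", "gamma")])
  expect_equal(ann$cell_type[ann$cluster == 0], "beta")
  expect_equal(ann$cell_type[ann$cluster == 1], "alpha")
  expect_true(ann$multi_hormone[ann$cluster == 4])
  expect_false(any(ann$multi_hormone[ann$cluster %in% 0:3]))
  expect_error(annotate_clusters(labels, nm, panel = character(0)), "empty")
})

test_that("the marker test is calibrated, powered, and equals a direct oracle", {
  set.seed(9)
  n <- 400
  labels <- rep(c("t", "r"), each = n / 2)
  nm <- matrix(rnorm(2 * n, mean = 1), 2,
               dimnames = list(c("null_gene", "marker"), sprintf("c%d", 1:n)))
  nm[2, labels == "t"] <- nm[2, labels == "t"] + 2
  nm <- pmax(nm, 0)
  res <- marker_de(nm, labels, "t", family = "logistic")
  expect_gt(res$p[res$gene_id == "null_gene"], 0.01)
  expect_lt(res$fdr[res$gene_id == "marker"], 0.01)

  # oracle: direct likelihood maximization of the logistic models
  y <- as.numeric(labels == "t")
  nll <- function(beta, X) {
    eta <- X %*% beta
    sum(log(1 + exp(eta))) - sum(y * eta)
  }
  X1 <- cbind(1, nm[1, ])
  f1 <- optim(c(0, 0), nll, X = X1, method = "BFGS")
  f0 <- optim(0, function(b) nll(b, matrix(1, n)), method = "BFGS")
  lrt_oracle <- 2 * (f0$value - f1$value)
  expect_equal(res$stat[res$gene_id == "null_gene"], lrt_oracle,
               tolerance = 1e-6)
})

test_that("marker test type-I error is controlled on null data", {
  set.seed(10)
  n <- 200
  labels <- rep(c("t", "r"), each = n / 2)
  nm <- matrix(abs(rnorm(500 * n)), 500,
               dimnames = list(sprintf("g%d", 1:500), sprintf("c%d", 1:n)))
  res <- marker_de(nm, labels, "t", family = "logistic")
  expect_lte(mean(res$fdr <= 0.01), 0.02)
})
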
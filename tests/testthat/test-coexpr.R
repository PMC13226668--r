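test_that("covariate residualization is exact OLS with preserved means", {
  set.seed(20)
  n <- 30
  cov <- data.frame(sex = rep(c("F", "M"), each = n / 2),
                    age = rnorm(n))
  X <- model.matrix(~ ., cov)
  expr <- matrix(rnorm(n * 10), n, dimnames = list(NULL,
                                                   sprintf("g%d", 1:10)))
  # planted sex offset is removed to numerical precision
  expr_off <- expr
  expr_off[cov$sex == "M", 1] <- expr_off[cov$sex == "M", 1] + 2
  res <- residualize_covariates(expr_off, cov)
  fit <- lm(res[, 1] ~ cov$sex)
  expect_lt(abs(coef(fit)[2]), 1e-8)

  # residuals orthogonal to every covariate column
  centered <- sweep(res, 2, colMeans(res))
  expect_lt(max(abs(crossprod(X[, -1], centered))), 1e-8)

  # expression already orthogonal to the covariates: identity
  ortho <- residualize_covariates(expr, cov)      # orthogonalize once
  again <- residualize_covariates(ortho, cov)
  expect_equal(again, ortho, tolerance = 1e-10)
})

test_that("signed adjacency lies in [0,1] and is monotone in the power", {
  set.seed(21)
  expr <- matrix(rnorm(20 * 40), 20, dimnames = list(NULL,
                                                     sprintf("g%d", 1:40)))
  a1 <- signed_adjacency(expr, 1)
  a6 <- signed_adjacency(expr, 6)
  expect_true(all(a1 >= 0 & a1 <= 1))
  expect_true(all(a6 <= a1 + 1e-12))
})

test_that("the soft-threshold scan finds scale-free structure where planted", {
  set.seed(22)
  # hub-structured expression: power-law loadings onto one latent factor
  n <- 60; g <- 300
  f <- rnorm(n)
  load <- (1:g)^(-0.6)
  expr <- f %*% t(load) + matrix(rnorm(n * g, sd = 0.6), n)
  colnames(expr) <- sprintf("g%03d", 1:g)
  scan <- soft_threshold_scan(expr, grid = c(1, 2, 4, 6, 9, 12))
  expect_gt(max(scan$sft_r2), 0.8)
  expect_true(all(diff(scan$mean_connectivity) < 0))

  # uncorrelated noise at t = 1: weak fit, high connectivity
  noise <- matrix(rnorm(n * 100), n,
                  dimnames = list(NULL, sprintf("g%d", 1:100)))
  scn <- soft_threshold_scan(noise, grid = 1)
  expect_lt(scn$sft_r2[1], 0.8)
  expect_gt(scn$mean_connectivity[1], 20)
})

test_that("TOM matches hand evaluation and the brute-force oracle", {
  a <- matrix(c(0, .5, .5, .5, 0, 0, .5, 0, 0), 3)
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 0.5)  # (0 + .5) / (min(1, .5) + 1 - .5)
  expect_equal(diag(tom), rep(1, 3))

  # identical-neighbourhood pair with a_ij = 1 (full triangle)
  b <- matrix(1, 3, 3); diag(b) <- 0
  expect_equal(tom_similarity(b)[1, 2], 1)

  set.seed(23)
  r <- matrix(runif(400), 20); r <- (r + t(r)) / 2; diag(r) <- 0
  expect_equal(tom_similarity(r), tom_oracle(r), tolerance = 1e-12)
  expect_error(tom_similarity(matrix(runif(9), 3)), "symmetric")
})

test_that("module detection recovers planted blocks and sends noise to grey", {
  sim <- simulate_module_expression(n_samples = 40, n_block_genes = 60,
                                    n_blocks = 3, n_noise = 120, seed = 3)
  adj <- signed_adjacency(sim$expr, 6)
  tom <- tom_similarity(adj)
  part <- detect_modules(1 - tom, sim$expr, min_module_size = 30)
  assigned <- part$modules != "grey"
  truth_block <- sim$truth$block
  # noise genes overwhelmingly grey, blocks recovered
  expect_gt(mean(part$modules[truth_block == 0] == "grey"), 0.9)
  ari <- adjusted_rand_index(part$modules[truth_block > 0],
                             truth_block[truth_block > 0])
  expect_gte(ari, 0.9)

  # merge_cut_height = 0: no merging happens
  p0 <- detect_modules(1 - tom, sim$expr, min_module_size = 30,
                       merge_cut_height = 0)
  expect_gte(length(setdiff(unique(p0$modules), "grey")),
             length(setdiff(unique(part$modules), "grey")))

  # two near-identical blocks merge
  f <- rnorm(40)
  twin <- cbind(f %*% t(runif(40, .7, .9)) + matrix(rnorm(1600, sd = .4), 40),
                f %*% t(runif(40, .7, .9)) + matrix(rnorm(1600, sd = .4), 40))
  colnames(twin) <- sprintf("g%d", 1:80)
  tomt <- tom_similarity(signed_adjacency(twin, 6))
  pt <- detect_modules(1 - tomt, twin, min_module_size = 20)
  expect_equal(length(setdiff(unique(pt$modules), "grey")), 1)
})

test_that("eigengenes are the leading singular direction, oriented and optimal", {
  set.seed(24)
  f <- rnorm(30)
  expr <- cbind(f %*% t(rep(1, 10)) + matrix(rnorm(300, sd = .1), 30))
  colnames(expr) <- sprintf("g%d", 1:10)
  eg <- module_eigengene(expr, rep("M1", 10))
  # perfectly correlated module: eigengene proportional to any member
  expect_gt(abs(cor(eg[, 1], expr[, 1])), 0.99)
  expect_gte(cor(eg[, 1], rowMeans(scale(expr))), 0)
  expect_equal(sum(eg[, 1]^2), 1)

  # optimality: explains at least as much variance as random unit vectors
  Z <- scale(expr)
  var_along <- function(v) sum((Z %*% t(Z) %*% v) * v)
  best <- var_along(eg[, 1])
  for (i in 1:20) {
    v <- rnorm(30); v <- v / sqrt(sum(v^2))
    expect_gte(best + 1e-8, var_along(v))
  }
})

test_that("module-trait correlation is Spearman with exact rank behaviour", {
  set.seed(25)
  eg <- cbind(M1 = rnorm(20))
  traits <- data.frame(hba1c = exp(eg[, 1]) + 5)   # monotone transform
  mt <- module_trait_correlation(eg, traits)
  expect_equal(mt$rho, 1)

  traits2 <- data.frame(x = rnorm(20))
  mt2 <- module_trait_correlation(eg, traits2)
  expect_equal(mt2$rho, spearman_oracle(eg[, 1], traits2$x),
               tolerance = 1e-12)

  expect_warning(module_trait_correlation(eg, data.frame(k = rep(1, 20))),
                 "constant")
})

test_that("expressed-gene filtering uses a strict donor threshold", {
  counts <- rbind(a = c(1, 1, 1), b = c(1, 1, 0), c = c(0, 0, 0))
  expect_equal(filter_expressed_genes(counts, min_donors = 2), "a")
})
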
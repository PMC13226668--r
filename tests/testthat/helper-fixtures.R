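# shared fixtures, built in code

# tiny counts matrix: genes x droplets from a dense matrix
tiny_counts <- function(m, genes = NULL, cells = NULL, lib = "LIB") {
  m <- as.matrix(m)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(ncol(m)))
  counts_matrix(m, genes, cells, lib)
}

# small synthetic cohort used by several unit tests (seconds, not minutes)
small_sim_config <- function(seed = 7) {
  sim_config(seed = seed, cells_per_donor = 80L, n_genes = 400L,
             n_empty_droplets = 20000L, n_variants = 60L,
             n_planted_deg = 16L, n_modules = 2L, module_size = 15L)
}

.fixture_env <- new.env(parent = emptyenv())

# memoized default cohort shared by the acceptance blocks
default_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- simulate_cohort(sim_config())
  .fixture_env$cohort
}

small_cohort <- function() {
  if (is.null(.fixture_env$small))
    .fixture_env$small <- simulate_cohort(small_sim_config())
  .fixture_env$small
}

# brute-force two-sided Fisher p: sum of hypergeometric point masses <= observed
fisher_oracle <- function(tab) {
  x <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  dens <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(x, m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# triple-loop TOM oracle
tom_oracle <- function(a) {
  g <- nrow(a)
  k <- colSums(a)
  tom <- diag(g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (i == j) next
    l <- sum(a[i, ] * a[, j])
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# direct-definition BH adjustment
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Spearman rho as rank-then-Pearson
spearman_oracle <- function(x, y) stats::cor(rank(x), rank(y))
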
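#' Synthetic islet cohort configuration
#'
#' Returns the full parameter set of the synthetic cohort generator. Defaults
#' encode the study conditions every downstream stage assumes: negative
#' binomial counts with cell-type marker structure, state-dependent beta-cell
#' composition (endocrine-restricted means 55.2% ND / 57.2% PD / 42.2% T2D,
#' Dirichlet concentration giving sd ~ 11), HbA1c group means 5.2 / 5.9 / 7.6%,
#' multiplicative ambient contamination with per-cell fraction rho ~ Beta
#' (mean 0.08), empty droplets, 10% cross-cell doublets, genotype pileups with
#' 1% base-call error, and planted T2D beta-cell DEGs at |log2FC| = 1.
#'
#' @param seed integer seed governing every random draw.
#' @param n_donors integer triple: donors per `ND`, `PD`, `T2D` state.
#' @param cells_per_donor cells simulated per donor.
#' @param n_genes total gene universe (markers and mito genes included).
#' @param nb_dispersion NB dispersion (1/size); 0 is the Poisson limit.
#' @param libsize_meanlog,libsize_sdlog lognormal per-cell library size.
#' @param rho_shape1,rho_shape2 Beta parameters of the contamination fraction
#'   (defaults mean 0.08).
#' @param rho_type_multipliers named per-cell-type multipliers of the
#'   contamination fraction. Ambient load per droplet is roughly constant
#'   while endogenous library size differs by cell type, so the ambient
#'   share varies with cell type; the defaults span 0.5-1.6 around an
#'   abundance-weighted mean near 1, keeping the cohort-wide mean near 0.08.
#' @param n_empty_droplets empty (pure-soup) droplets added per library.
#' @param empty_total_mean Poisson mean of empty-droplet totals.
#' @param doublet_rate fraction of cells merged into cross-cell doublets.
#' @param n_planted_deg number of beta-cell T2D DEGs planted (half up, half
#'   down) at effect `deg_log2fc`.
#' @param deg_log2fc planted log2 fold change magnitude.
#' @param n_modules,module_size,module_factor_sd planted donor-level
#'   co-expression blocks in beta cells.
#' @param n_variants,allele_freq_range,reads_per_variant,base_error genotype
#'   pileup model for demultiplexing.
#' @param hba1c_mean,hba1c_sd named per-state HbA1c distributions (%).
#' @param n_evidence evidence genes planted per concordance class.
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_donors = c(ND = 2L, PD = 2L, T2D = 2L),
                       cells_per_donor = 500L,
                       n_genes = 2000L,
                       nb_dispersion = 0.4,
                       libsize_meanlog = log(2500), libsize_sdlog = 0.35,
                       rho_shape1 = 2, rho_shape2 = 23,
                       rho_type_multipliers = c(beta = 0.8, alpha = 1.1,
                                                delta = 1.4, gamma = 1.6,
                                                acinar = 0.5, ductal = 0.6),
                       n_empty_droplets = 350000L,
                       empty_total_mean = 3,
                       doublet_rate = 0.10,
                       n_planted_deg = 40L,
                       deg_log2fc = 1,
                       n_modules = 3L, module_size = 40L,
                       module_factor_sd = 0.5,
                       n_variants = 100L,
                       allele_freq_range = c(0.2, 0.8),
                       reads_per_variant = 0.5,
                       base_error = 0.01,
                       hba1c_mean = c(ND = 5.2, PD = 5.9, T2D = 7.6),
                       hba1c_sd = c(ND = 0.3, PD = 0.2, T2D = 0.3),
                       n_evidence = c(concordant = 6L, discordant = 4L,
                                      mixed = 3L)) {
  stopifnot(doublet_rate < 1, all(n_donors >= 0), n_genes >= 200,
            nb_dispersion >= 0, base_error > 0, base_error <= 0.5)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# endocrine-restricted composition means per state; exocrine fixed at 8%
.state_composition <- function(state) {
  endo <- switch(state,
    ND  = c(beta = 0.552, alpha = 0.358, delta = 0.055, gamma = 0.035),
    PD  = c(beta = 0.572, alpha = 0.357, delta = 0.047, gamma = 0.024),
    T2D = c(beta = 0.422, alpha = 0.487, delta = 0.056, gamma = 0.035))
  c(endo * 0.92, acinar = 0.05, ductal = 0.03)
}

.cell_types <- c("beta", "alpha", "delta", "gamma", "acinar", "ductal")
.hormone_markers <- c(beta = "INS", alpha = "GCG", delta = "SST",
                      gamma = "PPY")
.type_markers <- c(.hormone_markers, acinar = "REG1B", ductal = "KRT19")
.mito_genes <- c("MT-ND1", "MT-CO1", "MT-CYB", "MT-ATP6", "MT-ND4")

#' Gene universe of the synthetic cohort
#' @param cfg a [sim_config()].
#' @return character vector of `cfg$n_genes` gene identifiers, beginning with
#'   the cell-type markers and mitochondrial genes.
#' @export
sim_gene_ids <- function(cfg) {
  named <- c(unname(.type_markers), .mito_genes)
  c(named, sprintf("GENE%04d", seq_len(cfg$n_genes - length(named))))
}

# genes x types relative-expression profiles; markers get a large share of
# their own type's mass, each type additionally elevates a private program of
# genes (for HVG/clustering separation), mito genes carry a small shared share
.build_profiles <- function(cfg) {
  genes <- sim_gene_ids(cfg)
  g <- length(genes)
  base <- stats::rlnorm(g, 0, 1.2)
  names(base) <- genes
  base[.mito_genes] <- sum(base) * 0.015          # ~7% mito mass total
  prof <- matrix(base, g, length(.cell_types),
                 dimnames = list(genes, .cell_types))
  marker_share <- c(beta = 0.25, alpha = 0.20, delta = 0.20, gamma = 0.20,
                    acinar = 0.15, ductal = 0.10)
  free <- setdiff(genes, c(.type_markers, .mito_genes))
  program <- split(sample(free, 30 * length(.cell_types)),
                   rep(.cell_types, each = 30))
  for (ty in .cell_types) {
    prof[program[[ty]], ty] <- prof[program[[ty]], ty] * 8
    p <- prof[, ty]
    p[unname(.type_markers)] <- 0            # markers are type-exclusive
    p <- p / sum(p) * (1 - marker_share[ty])
    p[.type_markers[ty]] <- marker_share[ty]
    prof[, ty] <- p
  }
  sweep(prof, 2, colSums(prof), "/")
}

.plant_degs <- function(cfg, genes) {
  if (cfg$n_planted_deg == 0)
    return(tibble::tibble(gene_id = character(), cell_type = character(),
                          state = character(), log2fc = numeric()))
  free <- setdiff(genes, c(.type_markers, .mito_genes))
  picked <- sample(free, cfg$n_planted_deg)
  n_up <- ceiling(cfg$n_planted_deg / 2)
  tibble::tibble(gene_id = picked, cell_type = "beta", state = "T2D",
                 log2fc = rep(c(cfg$deg_log2fc, -cfg$deg_log2fc),
                              c(n_up, cfg$n_planted_deg - n_up)))
}

.plant_modules <- function(cfg, genes, deg_genes) {
  if (cfg$n_modules == 0)
    return(tibble::tibble(gene_id = character(), module = integer()))
  free <- setdiff(genes, c(.type_markers, .mito_genes, deg_genes))
  picked <- sample(free, cfg$n_modules * cfg$module_size)
  tibble::tibble(gene_id = picked,
                 module = rep(seq_len(cfg$n_modules), each = cfg$module_size))
}

#' Simulate donor metadata
#'
#' HbA1c is drawn around the per-state group means (ND 5.2, PD 5.9, T2D 7.6 by
#' default); age and BMI come from one shared distribution so groups are
#' matched; sex, ancestry and chemistry are categorical draws. Chemistry is
#' assigned per library (the first library is V2, the rest V3).
#'
#' @param cfg a [sim_config()].
#' @return tibble of donor records with a `library_id` pairing column.
#' @export
simulate_donor_metadata <- function(cfg) {
  set.seed(cfg$seed + 101L)
  states <- rep(c("ND", "PD", "T2D"), cfg$n_donors[c("ND", "PD", "T2D")])
  n <- length(states)
  states <- states[order(stats::runif(n))]  # shuffle so libraries mix states
  donors <- tibble::tibble(
    donor_id = sprintf("D%02d", seq_len(n)),
    state = factor(states, levels = c("ND", "PD", "T2D")),
    hba1c = stats::rnorm(n, cfg$hba1c_mean[states], cfg$hba1c_sd[states]),
    age = round(stats::rnorm(n, 55, 10)),
    bmi = round(stats::rnorm(n, 30, 4), 1),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.4, 0.6)),
    ancestry = sample(c("EUR", "HISP", "AFR"), n, replace = TRUE,
                      prob = c(0.5, 0.35, 0.15)))
  donors$hba1c <- pmax(donors$hba1c, 4)
  # multiplex donors pairwise into libraries
  lib_of <- ceiling(seq_len(n) / 2)
  donors$library_id <- sprintf("LIB%02d", lib_of)
  donors$chemistry <- ifelse(lib_of == 1L, "V2", "V3")
  donors
}

#' Simulate true (uncontaminated) per-library counts
#'
#' Cell types are drawn per donor from a Dirichlet whose beta-cell mean follows
#' the donor's glycemic state; per-cell library sizes are lognormal; counts are
#' NB(mean = libsize x profile, dispersion = `nb_dispersion`). Planted DEGs
#' multiply the beta-cell mean by `2^log2fc` in the designated state, and
#' planted module genes are modulated by donor-level latent factors in beta
#' cells.
#'
#' @param cfg a [sim_config()].
#' @param donors output of [simulate_donor_metadata()].
#' @return list with `counts` (named list of [counts_matrix()] per library),
#'   `truth` (per-droplet tibble) and `genes` (per-gene truth tibble).
#' @export
simulate_true_counts <- function(cfg, donors) {
  set.seed(cfg$seed + 202L)
  genes <- sim_gene_ids(cfg)
  profiles <- .build_profiles(cfg)
  deg <- .plant_degs(cfg, genes)
  modules <- .plant_modules(cfg, genes, deg$gene_id)
  conc <- 20
  size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf

  counts <- list(); truth <- list()
  for (lib in unique(donors$library_id)) {
    lib_donors <- donors[donors$library_id == lib, ]
    cols <- list(); meta <- list()
    for (di in seq_len(nrow(lib_donors))) {
      don <- lib_donors[di, ]
      comp_mean <- .state_composition(as.character(don$state))
      comp <- stats::rgamma(length(comp_mean), shape = conc * comp_mean)
      comp <- comp / sum(comp)
      types <- sample(.cell_types, cfg$cells_per_donor, replace = TRUE,
                      prob = comp)
      libsize <- stats::rlnorm(cfg$cells_per_donor, cfg$libsize_meanlog,
                               cfg$libsize_sdlog)
      # donor-specific beta profile: planted DEGs + module factors
      don_prof <- profiles
      if (nrow(deg) && as.character(don$state) == "T2D")
        don_prof[deg$gene_id, "beta"] <-
          don_prof[deg$gene_id, "beta"] * 2^deg$log2fc
      if (nrow(modules)) {
        f <- stats::rnorm(cfg$n_modules, 0, cfg$module_factor_sd)
        don_prof[modules$gene_id, "beta"] <-
          don_prof[modules$gene_id, "beta"] * 2^(f[modules$module])
      }
      mu <- don_prof[, types, drop = FALSE] %*% diag(libsize, length(libsize))
      x <- if (is.finite(size))
        stats::rnbinom(length(mu), size = size, mu = as.numeric(mu))
      else stats::rpois(length(mu), as.numeric(mu))
      cols[[di]] <- matrix(x, nrow = length(genes))
      meta[[di]] <- tibble::tibble(donor_id = don$donor_id,
                                   cell_type = types)
    }
    m <- do.call(cbind, cols)
    bc <- sprintf("%s-BC%05d", lib, seq_len(ncol(m)))
    counts[[lib]] <- counts_matrix(m, genes, bc, lib)
    truth[[lib]] <- dplyr::bind_rows(meta) |>
      dplyr::mutate(library_id = lib, barcode_id = bc,
                    doublet = FALSE, empty = FALSE, rho = 0)
  }
  gene_truth <- tibble::tibble(gene_id = genes) |>
    dplyr::left_join(deg |> dplyr::select(gene_id, deg_log2fc = log2fc),
                     by = "gene_id") |>
    dplyr::left_join(modules, by = "gene_id")
  list(counts = counts, truth = dplyr::bind_rows(truth), genes = gene_truth)
}

# multivariate hypergeometric removal of `k` UMIs from a count vector
.remove_umis <- function(cnt, k) {
  nz <- which(cnt > 0)
  pool <- rep.int(nz, cnt[nz])
  rm_idx <- pool[sample.int(length(pool), k)]
  rm <- tabulate(rm_idx, nbins = length(cnt))
  cnt - rm
}

#' Overlay ambient contamination and empty droplets
#'
#' The soup profile is the cohort-wide count-weighted gene frequency. For each
#' cell with total `N_c`, `Binomial(N_c, rho_c)` UMIs are removed uniformly and
#' replaced by multinomial soup draws, so totals are conserved. Pure-soup empty
#' droplets with small Poisson totals are appended.
#'
#' @param sim output of [simulate_true_counts()].
#' @param cfg a [sim_config()].
#' @return list with contaminated `counts`, updated `truth` (per-cell `rho`,
#'   `empty` flags) and the true `soup` profile (named numeric, per library).
#' @export
apply_ambient_and_empties <- function(sim, cfg) {
  set.seed(cfg$seed + 303L)
  genes <- sim$counts[[1]]$gene_ids
  counts <- sim$counts; truth <- sim$truth
  soup_list <- list()
  for (lib in names(counts)) {
    m <- as.matrix(counts[[lib]]$values)
    soup <- rowSums(m); soup <- soup / sum(soup)
    soup_list[[lib]] <- soup
    n_cells <- ncol(m)
    types <- truth$cell_type[truth$library_id == lib]
    mult <- cfg$rho_type_multipliers[types]
    mult[is.na(mult)] <- 1
    rho <- pmin(stats::rbeta(n_cells, cfg$rho_shape1, cfg$rho_shape2) *
                  unname(mult), 0.9)
    for (ci in seq_len(n_cells)) {
      N <- sum(m[, ci])
      k <- stats::rbinom(1, N, rho[ci])
      if (k > 0)
        m[, ci] <- .remove_umis(m[, ci], k) +
          as.integer(stats::rmultinom(1, k, soup))
    }
    tot <- stats::rpois(cfg$n_empty_droplets, cfg$empty_total_mean)
    gene_draw <- sample.int(length(soup), sum(tot), replace = TRUE,
                            prob = soup)
    emp <- Matrix::sparseMatrix(
      i = gene_draw, j = rep.int(seq_along(tot), tot), x = 1,
      dims = c(nrow(m), cfg$n_empty_droplets))
    bc_emp <- sprintf("%s-EMPTY%06d", lib, seq_len(cfg$n_empty_droplets))
    all_bc <- c(counts[[lib]]$barcode_ids, bc_emp)
    counts[[lib]] <- counts_matrix(
      cbind(methods::as(methods::as(m, "sparseMatrix"), "CsparseMatrix"),
            emp), genes, all_bc, lib)
    truth$rho[truth$library_id == lib] <- rho
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      donor_id = NA_character_, cell_type = NA_character_,
      library_id = lib, barcode_id = bc_emp, doublet = FALSE, empty = TRUE,
      rho = 1))
  }
  list(counts = counts, truth = truth, soup = soup_list, genes = sim$genes)
}

#' Merge random cell pairs into doublet droplets
#'
#' A `Binomial(C, doublet_rate)` number of doublets is formed per library;
#' each doublet replaces two uniformly chosen cell droplets with the sum of
#' their counts (UMIs are additive in a droplet), with cross-donor pairs
#' allowed in multiplexed libraries.
#'
#' @param sim output of [apply_ambient_and_empties()].
#' @param cfg a [sim_config()].
#' @return same shape as the input, with doublet droplets and truth flags; the
#'   truth gains `donor_id2`/`cell_type2` for the second parent.
#' @export
inject_doublets <- function(sim, cfg) {
  stopifnot(cfg$doublet_rate < 1)
  set.seed(cfg$seed + 404L)
  counts <- sim$counts
  truth <- sim$truth |>
    dplyr::mutate(donor_id2 = NA_character_, cell_type2 = NA_character_)
  if (cfg$doublet_rate == 0) {
    out <- sim; out$truth <- truth
    return(out)
  }
  for (lib in names(counts)) {
    cm <- counts[[lib]]
    is_cell <- with(truth, library_id == lib & !empty)
    cell_bc <- truth$barcode_id[is_cell]
    n_doub <- stats::rbinom(1, length(cell_bc), cfg$doublet_rate)
    if (n_doub == 0) next
    parents <- matrix(sample(cell_bc, 2 * n_doub), ncol = 2)
    m <- cm$values
    doub <- m[, parents[, 1], drop = FALSE] + m[, parents[, 2], drop = FALSE]
    bc_doub <- sprintf("%s-DBL%04d", lib, seq_len(n_doub))
    colnames(doub) <- bc_doub
    keep <- setdiff(cm$barcode_ids, as.vector(parents))
    counts[[lib]] <- counts_matrix(cbind(m[, keep, drop = FALSE], doub),
                                   cm$gene_ids, c(keep, bc_doub), lib)
    p1 <- truth[match(parents[, 1], truth$barcode_id), ]
    p2 <- truth[match(parents[, 2], truth$barcode_id), ]
    truth <- truth |>
      dplyr::filter(!(barcode_id %in% as.vector(parents))) |>
      dplyr::bind_rows(tibble::tibble(
        donor_id = p1$donor_id, cell_type = p1$cell_type,
        library_id = lib, barcode_id = bc_doub, doublet = TRUE,
        empty = FALSE, rho = (p1$rho + p2$rho) / 2,
        donor_id2 = p2$donor_id, cell_type2 = p2$cell_type))
  }
  out <- sim; out$counts <- counts; out$truth <- truth
  out
}

#' Simulate donor genotypes and per-droplet allele pileups
#'
#' Biallelic variants with allele frequencies in `allele_freq_range`; donor
#' genotypes drawn under Hardy-Weinberg; per droplet and variant, a Poisson
#' number of reads whose base calls follow the true donor's genotype (doublets:
#' 50/50 mixture of the two parents) and are flipped with probability
#' `base_error`.
#'
#' @param cfg a [sim_config()].
#' @param donors donor tibble.
#' @param truth per-droplet truth tibble (post [inject_doublets()]).
#' @return list with `genotypes` (tibble variant x donor dosage, long) and
#'   `pileups` (tibble droplet, variant, calls as counts of R/A).
#' @export
simulate_genotype_pileups <- function(cfg, donors, truth) {
  set.seed(cfg$seed + 505L)
  af <- stats::runif(cfg$n_variants, cfg$allele_freq_range[1],
                     cfg$allele_freq_range[2])
  vid <- sprintf("var%04d", seq_len(cfg$n_variants))
  geno <- tidyr::expand_grid(variant_id = vid, donor_id = donors$donor_id) |>
    dplyr::left_join(tibble::tibble(variant_id = vid, af = af),
                     by = "variant_id") |>
    dplyr::mutate(dosage = stats::rbinom(dplyr::n(), 2, af)) |>
    dplyr::select(variant_id, donor_id, dosage)
  # geno is ordered variant-major (donor varies fastest)
  gmat <- t(matrix(geno$dosage, nrow = nrow(donors),
                   dimnames = list(unique(geno$donor_id), vid)))

  drops <- truth[!truth$empty, ]
  out <- vector("list", nrow(drops))
  for (i in seq_len(nrow(drops))) {
    d <- drops[i, ]
    reads <- stats::rpois(cfg$n_variants, cfg$reads_per_variant)
    nz <- which(reads > 0)
    if (!length(nz)) next
    p_alt <- gmat[nz, d$donor_id] / 2
    if (isTRUE(d$doublet) && !is.na(d$donor_id2))
      p_alt <- (p_alt + gmat[nz, d$donor_id2] / 2) / 2
    alt <- stats::rbinom(length(nz), reads[nz], p_alt)
    ref <- reads[nz] - alt
    # base-call error: each call flips R<->A with probability base_error
    flip_a <- stats::rbinom(length(nz), alt, cfg$base_error)
    flip_r <- stats::rbinom(length(nz), ref, cfg$base_error)
    out[[i]] <- tibble::tibble(
      library_id = d$library_id, barcode_id = d$barcode_id,
      variant_id = vid[nz],
      n_ref = ref - flip_r + flip_a, n_alt = alt - flip_a + flip_r,
      n_other = 0L)
  }
  list(genotypes = geno, pileups = dplyr::bind_rows(out))
}

#' Simulate GWAS/LD/eQTL/protein/mouse evidence tables with planted classes
#'
#' For each planted-concordant gene a risk variant is emitted whose oriented
#' eQTL Z sign matches the gene's DEG sign, with direction string `++++` or
#' `----`; discordant genes get the opposite sign; mixed genes get two
#' independent signals (pairwise LD r-squared below the proxy threshold) with
#' opposite Z signs. A subset of index variants additionally gets a proxy at
#' r-squared >= 0.80. Protein and mouse-knockout rows agree with the planted
#' DEG direction.
#'
#' @param cfg a [sim_config()].
#' @param deg_truth tibble `gene_id`, `log2fc` of planted DEGs (the evidence
#'   genes are drawn from it).
#' @return list of tibbles `gwas`, `ld`, `eqtl`, `deg`, `protein`, `mouse`,
#'   `truth` (gene, planted class).
#' @export
simulate_evidence_tables <- function(cfg, deg_truth) {
  set.seed(cfg$seed + 606L)
  need <- sum(cfg$n_evidence)
  stopifnot(nrow(deg_truth) >= need)
  picked <- deg_truth[sample.int(nrow(deg_truth), need), ]
  classes <- rep(names(cfg$n_evidence), cfg$n_evidence)
  gwas <- list(); eqtl <- list(); ld <- list(); vctr <- 0L
  new_var <- function() {
    vctr <<- vctr + 1L
    sprintf("rs%05d", vctr)
  }
  for (i in seq_len(need)) {
    g <- picked$gene_id[i]; lfc <- picked$log2fc[i]; cl <- classes[i]
    n_sig <- if (cl == "mixed") 2L else 1L
    signs <- switch(cl,
                    concordant = sign(lfc),
                    discordant = -sign(lfc),
                    mixed = c(sign(lfc), -sign(lfc)))
    for (s in seq_len(n_sig)) {
      v <- new_var()
      gwas[[length(gwas) + 1L]] <- tibble::tibble(
        variant_id = v, risk_allele = "A", other_allele = "G",
        odds_ratio = stats::runif(1, 1.03, 1.2), p = 5e-9,
        locus_id = sprintf("locus_%s_%d", g, s))
      eqtl[[length(eqtl) + 1L]] <- tibble::tibble(
        variant_id = v, effect_allele = "A", gene = g,
        z = signs[s] * stats::runif(1, 2, 4), p = stats::runif(1, 1e-4, 0.04),
        cohort_directions = if (signs[s] > 0) "++++" else "----")
      if (s == 1 && i %% 2 == 1) {            # proxy for odd-indexed signals
        pv <- new_var()
        ld[[length(ld) + 1L]] <- tibble::tibble(
          variant_id1 = v, variant_id2 = pv,
          r2 = stats::runif(1, 0.80, 0.99), aligned_allele = "A")
      }
    }
    if (cl == "mixed")       # record the two signals' independence
      ld[[length(ld) + 1L]] <- tibble::tibble(
        variant_id1 = sprintf("rs%05d", vctr - 1L),
        variant_id2 = sprintf("rs%05d", vctr),
        r2 = stats::runif(1, 0.05, 0.30), aligned_allele = "A")
  }
  protein <- tibble::tibble(
    gene = picked$gene_id,
    log2fc_protein = sign(picked$log2fc) * stats::runif(need, 0.3, 1.5),
    p = stats::runif(need, 0.001, 0.04))
  mouse <- tibble::tibble(
    gene = picked$gene_id,
    phenotype = "glucose_tolerance",
    direction = ifelse(picked$log2fc < 0, "impaired", "improved"))
  list(gwas = dplyr::bind_rows(gwas), ld = dplyr::bind_rows(ld),
       eqtl = dplyr::bind_rows(eqtl),
       deg = picked |> dplyr::select(gene = gene_id, log2fc),
       protein = protein, mouse = mouse,
       truth = tibble::tibble(gene = picked$gene_id, class = classes))
}

#' Generate the full synthetic cohort
#'
#' Runs every generator stage in order and returns the cohort bundle plus the
#' complete ground truth. Two calls with the same configuration give identical
#' output.
#'
#' @param cfg a [sim_config()].
#' @return list with `raw` / `filtered` counts per library, `donors`, `truth`
#'   (droplet truth), `genes` (gene truth), `soup` (per-library true profile),
#'   `genotypes`, `pileups`, `evidence`, `library_donors`, and `bundle`
#'   (a [cohort_bundle()] passing [validate_cohort()]).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  donors <- simulate_donor_metadata(cfg)
  sim <- simulate_true_counts(cfg, donors)
  sim <- apply_ambient_and_empties(sim, cfg)
  sim <- inject_doublets(sim, cfg)
  gp <- simulate_genotype_pileups(cfg, donors, sim$truth)
  deg_rows <- sim$genes |> dplyr::filter(!is.na(deg_log2fc)) |>
    dplyr::transmute(gene_id, log2fc = deg_log2fc)
  evidence <- simulate_evidence_tables(cfg, deg_rows)
  filtered <- purrr::imap(sim$counts, function(cm, lib) {
    keep <- sim$truth$barcode_id[sim$truth$library_id == lib &
                                   !sim$truth$empty]
    counts_matrix(cm$values[, keep, drop = FALSE], cm$gene_ids, keep, lib)
  })
  lib_don <- donors |> dplyr::select(library_id, donor_id)
  cells <- compute_cell_metrics_multi(filtered, mito_genes = .mito_genes)
  bundle <- cohort_bundle(sim$counts, filtered, cells, donors, lib_don)
  list(raw = sim$counts, filtered = filtered, donors = donors,
       truth = sim$truth, genes = sim$genes, soup = sim$soup,
       genotypes = gp$genotypes, pileups = gp$pileups, evidence = evidence,
       library_donors = lib_don, bundle = bundle)
}

#' Simulate pseudobulk NB counts for calibration studies
#'
#' Direct per-donor pseudobulk simulator used to study false-discovery control
#' and power of the NB-GLM at realistic donor numbers without generating
#' single cells.
#'
#' @param n_per_group donors per group (two groups, e.g. ND and T2D).
#' @param n_genes number of genes.
#' @param planted tibble `gene` (index), `log2fc` of planted effects in group
#'   2; `NULL` for a null simulation.
#' @param dispersion NB dispersion.
#' @param libsize_meanlog,libsize_sdlog lognormal library sizes.
#' @param seed integer seed.
#' @return list `counts` (genes x samples), `design` tibble with `state` and
#'   nuisance covariates.
#' @export
simulate_pseudobulk <- function(n_per_group = 17, n_genes = 400,
                                planted = NULL, dispersion = 0.15,
                                libsize_meanlog = log(5e5),
                                libsize_sdlog = 0.25, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  state <- factor(rep(c("ND", "T2D"), each = n_per_group),
                  levels = c("ND", "T2D"))
  base <- stats::rlnorm(n_genes, log(100), 1)
  libsize <- stats::rlnorm(n, libsize_meanlog, libsize_sdlog)
  rel <- base / sum(base)
  mu <- outer(rel, libsize)
  if (!is.null(planted))
    mu[planted$gene, state == "T2D"] <-
      mu[planted$gene, state == "T2D"] * 2^planted$log2fc
  counts <- matrix(stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu),
                   n_genes, n,
                   dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                                   sprintf("S%02d", seq_len(n))))
  design <- tibble::tibble(
    sample_id = colnames(counts), state = state,
    chemistry = sample(c("V2", "V3"), n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    ancestry = sample(c("EUR", "HISP"), n, replace = TRUE),
    age_scaled = as.numeric(scale(stats::rnorm(n, 55, 10))),
    bmi_scaled = as.numeric(scale(stats::rnorm(n, 30, 4))))
  list(counts = counts, design = design)
}

#' Simulate sample-by-gene expression with planted co-expression blocks
#'
#' Latent-factor model for testing module detection: each planted block shares
#' one standard-normal factor per sample with loadings in `[0.6, 0.95]`; noise
#' genes are independent. Returns genes in columns.
#'
#' @param n_samples,n_block_genes,n_blocks,n_noise dimensions.
#' @param seed integer seed.
#' @return list `expr` (samples x genes), `truth` (gene, block; 0 = noise),
#'   `factors` (samples x blocks latent factors).
#' @export
simulate_module_expression <- function(n_samples = 40, n_block_genes = 120,
                                       n_blocks = 3, n_noise = 200,
                                       seed = 1) {
  set.seed(seed)
  fac <- matrix(stats::rnorm(n_samples * n_blocks), n_samples, n_blocks)
  blocks <- list()
  for (b in seq_len(n_blocks)) {
    load <- stats::runif(n_block_genes, 0.6, 0.95)
    blocks[[b]] <- fac[, b] %*% t(load) +
      matrix(stats::rnorm(n_samples * n_block_genes,
                          sd = sqrt(1 - 0.8^2)), n_samples)
  }
  noise <- matrix(stats::rnorm(n_samples * n_noise), n_samples)
  expr <- cbind(do.call(cbind, blocks), noise)
  colnames(expr) <- sprintf("G%04d", seq_len(ncol(expr)))
  truth <- tibble::tibble(
    gene_id = colnames(expr),
    block = c(rep(seq_len(n_blocks), each = n_block_genes),
              rep(0L, n_noise)))
  list(expr = expr, truth = truth, factors = fac)
}
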
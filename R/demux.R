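#' Base-call likelihood given a genotype dosage
#'
#' With alt-allele dosage `g` in 0/1/2 and per-call error probability `eps`:
#' `P(A|g) = (g/2)(1-eps) + (1-g/2) eps`, `P(R|g)` symmetric, and any other
#' base has the catch-all probability `eps`.
#'
#' @param b base call, one of `"R"`, `"A"`, `"O"`.
#' @param g dosage in `{0, 1, 2}`.
#' @param eps error probability in `(0, 0.5]`.
#' @return probability.
#' @export
read_call_likelihood <- function(b, g, eps) {
  stopifnot(g %in% 0:2, eps > 0, eps <= 0.5)
  switch(b,
         A = (g / 2) * (1 - eps) + (1 - g / 2) * eps,
         R = (1 - g / 2) * (1 - eps) + (g / 2) * eps,
         O = eps,
         stop("base call must be R, A or O", call. = FALSE))
}

# donor dosages -> genotype posterior matrix (variants x 3), near-certain
.dosage_posteriors <- function(genotypes, variant_ids, certainty = 1 - 1e-12) {
  donors <- unique(genotypes$donor_id)
  slack <- (1 - certainty) / 2
  out <- lapply(donors, function(d) {
    g <- genotypes$dosage[genotypes$donor_id == d][
      match(variant_ids, genotypes$variant_id[genotypes$donor_id == d])]
    p <- matrix(slack, length(variant_ids), 3)
    p[cbind(seq_along(g), g + 1L)] <- certainty
    p
  })
  names(out) <- donors
  out
}

# per-variant call-count matrix for one droplet, aligned to variant_ids
.align_pileup <- function(pu, variant_ids) {
  i <- match(pu$variant_id, variant_ids)
  keep <- !is.na(i)
  m <- matrix(0, length(variant_ids), 3,
              dimnames = list(NULL, c("R", "A", "O")))
  m[i[keep], ] <- as.matrix(pu[keep, c("n_ref", "n_alt", "n_other")])
  list(counts = m, n_skipped = sum(!keep))
}

#' Log-likelihood of a droplet under a donor (pair) hypothesis
#'
#' Evaluates `log prod_v sum_{g1,g2} [ prod_i ((1-alpha) P(b_i|g1) +
#' alpha P(b_i|g2)) ] P_m1(g1) P_m2(g2)`. With `m1 == m2` and `alpha = 0`
#' this is the singlet likelihood.
#'
#' @param pileup tibble with `variant_id`, `n_ref`, `n_alt`, `n_other` for one
#'   droplet.
#' @param m1,m2 donor identifiers.
#' @param alpha mixing proportion of `m2` in `(1-alpha):alpha`.
#' @param genotypes tibble `variant_id`, `donor_id`, `dosage`.
#' @param eps base-call error probability.
#' @return log-likelihood (0 for an empty pileup).
#' @export
assignment_loglik <- function(pileup, m1, m2, alpha, genotypes, eps = 0.01) {
  vids <- unique(genotypes$variant_id)
  post <- .dosage_posteriors(genotypes, vids)
  al <- .align_pileup(pileup, vids)
  .loglik_counts(al$counts, post[[m1]], post[[m2]], alpha, eps)
}

.loglik_counts <- function(counts, p1, p2, alpha, eps) {
  used <- which(rowSums(counts) > 0)
  if (!length(used)) return(0)
  cn <- counts[used, , drop = FALSE]
  pa <- c(eps, 0.5, 1 - eps)          # P(A | g = 0,1,2)
  pr <- c(1 - eps, 0.5, eps)
  lik <- 0
  total <- numeric(length(used))
  for (g1 in 1:3) for (g2 in 1:3) {
    ma <- (1 - alpha) * pa[g1] + alpha * pa[g2]
    mr <- (1 - alpha) * pr[g1] + alpha * pr[g2]
    lv <- cn[, "R"] * log(mr) + cn[, "A"] * log(ma) + cn[, "O"] * log(eps)
    total <- total + exp(lv) * p1[used, g1] * p2[used, g2]
  }
  sum(log(total))
}

#' Assign one droplet to a donor or donor pair
#'
#' Evaluates every singlet and every unordered donor pair over `alpha_grid`;
#' the call is a doublet only when the best doublet log-likelihood beats the
#' best singlet by at least `doublet_margin` nats, and ambiguous when fewer
#' than `min_calls` informative calls are available.
#'
#' @param pileup droplet pileup tibble (`variant_id`, `n_ref`, `n_alt`,
#'   `n_other`).
#' @param genotypes tibble `variant_id`, `donor_id`, `dosage`.
#' @param donors candidate donor ids.
#' @param alpha_grid mixing fractions evaluated for doublets.
#' @param doublet_margin nats by which a doublet must beat the best singlet.
#' @param min_calls minimum informative calls for a confident call.
#' @param eps base-call error probability.
#' @return one-row tibble: `best_type`, `donor1`, `donor2`, `loglik`,
#'   `margin`.
#' @export
assign_droplet <- function(pileup, genotypes, donors, alpha_grid = 0.5,
                           doublet_margin = 2, min_calls = 3, eps = 0.01) {
  stopifnot(length(donors) >= 1)
  vids <- unique(genotypes$variant_id)
  post <- .dosage_posteriors(genotypes, vids)
  al <- .align_pileup(pileup, vids)
  .assign_droplet_counts(al$counts, post, donors, alpha_grid, doublet_margin,
                         min_calls, eps)
}

.assign_droplet_counts <- function(counts, post, donors, alpha_grid,
                                   doublet_margin, min_calls, eps) {
  n_calls <- sum(counts)
  if (n_calls < min_calls)
    return(tibble::tibble(best_type = "ambiguous", donor1 = NA_character_,
                          donor2 = NA_character_, loglik = NA_real_,
                          margin = 0, n_calls = n_calls))
  sing <- vapply(donors, function(d)
    .loglik_counts(counts, post[[d]], post[[d]], 0, eps), numeric(1))
  best_s <- which.max(sing)
  cand_ll <- sing
  doub <- NULL
  if (length(donors) >= 2) {
    pairs <- utils::combn(donors, 2)
    doub <- apply(pairs, 2, function(pr)
      max(vapply(alpha_grid, function(a)
        .loglik_counts(counts, post[[pr[1]]], post[[pr[2]]], a, eps),
        numeric(1))))
  }
  if (!is.null(doub) && max(doub) >= sing[best_s] + doublet_margin) {
    bi <- which.max(doub)
    all_ll <- sort(c(sing, doub), decreasing = TRUE)
    tibble::tibble(best_type = "doublet",
                   donor1 = pairs[1, bi], donor2 = pairs[2, bi],
                   loglik = doub[bi], margin = all_ll[1] - all_ll[2],
                   n_calls = n_calls)
  } else {
    runner <- if (length(sing) > 1)
      max(sing[-best_s]) else -Inf
    tibble::tibble(best_type = "singlet", donor1 = donors[best_s],
                   donor2 = NA_character_, loglik = sing[best_s],
                   margin = sing[best_s] - runner, n_calls = n_calls)
  }
}

#' Demultiplex all droplets of a pooled library
#'
#' Assigns every droplet of a multiplexed (>= 2 donor) library and flags
#' cross-donor doublets for removal with reason `demux_doublet`.
#'
#' @param filtered [counts_matrix()] of the library's cell droplets.
#' @param pileups pileup tibble for this library (`barcode_id`, `variant_id`,
#'   `n_ref`, `n_alt`, `n_other`).
#' @param genotypes tibble `variant_id`, `donor_id`, `dosage`.
#' @param donors donor ids multiplexed in this library.
#' @inheritParams assign_droplet
#' @return tibble, one row per droplet: `barcode_id`, `best_type`, `donor1`,
#'   `donor2`, `loglik`, `margin`, `filtered`, `reason`.
#' @export
demux_library <- function(filtered, pileups, genotypes, donors,
                          alpha_grid = 0.5, doublet_margin = 2,
                          min_calls = 3, eps = 0.01) {
  if (length(donors) < 2)
    stop("library is not multiplexed (needs >= 2 donors)", call. = FALSE)
  vids <- unique(genotypes$variant_id)
  post <- .dosage_posteriors(genotypes, vids)
  by_bc <- split(pileups, pileups$barcode_id)
  res <- purrr::map(filtered$barcode_ids, function(bc) {
    pu <- by_bc[[bc]]
    counts <- if (is.null(pu))
      matrix(0, length(vids), 3, dimnames = list(NULL, c("R", "A", "O")))
    else .align_pileup(pu, vids)$counts
    .assign_droplet_counts(counts, post, donors, alpha_grid, doublet_margin,
                           min_calls, eps) |>
      dplyr::mutate(barcode_id = bc, .before = 1)
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(
      library_id = filtered$library_id,
      filtered = best_type == "doublet",
      reason = dplyr::if_else(best_type == "doublet", "demux_doublet",
                              NA_character_))
}
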
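#' Expand GWAS index variants by LD proxies
#'
#' Single-hop closure: every variant linked to an index variant at
#' `r2 >= r2_min` (default 0.80) joins the set, inheriting the index's
#' risk-allele orientation through the LD table's aligned-allele column when
#' present; proxies without phase information are flagged
#' orientation-unknown. No transitive chaining.
#'
#' @param gwas tibble of index variants (`variant_id`, `risk_allele`,
#'   `other_allele`, `odds_ratio`, `p`, `locus_id`).
#' @param ld tibble `variant_id1`, `variant_id2`, `r2`, optional
#'   `aligned_allele`; symmetrized internally.
#' @param r2_min inclusion threshold (boundary inclusive).
#' @return tibble of variants with `index_variant`, `is_proxy`,
#'   `orientation_known`.
#' @export
expand_ld_proxies <- function(gwas, ld, r2_min = 0.80) {
  idx <- gwas |>
    dplyr::mutate(index_variant = variant_id, is_proxy = FALSE,
                  orientation_known = TRUE)
  if (is.null(ld) || !nrow(ld)) return(idx)
  if (!"aligned_allele" %in% names(ld)) ld$aligned_allele <- NA_character_
  sym <- dplyr::bind_rows(
    ld |> dplyr::select(a = variant_id1, b = variant_id2, r2,
                        aligned_allele),
    ld |> dplyr::select(a = variant_id2, b = variant_id1, r2,
                        aligned_allele))
  prox <- sym |>
    dplyr::filter(r2 >= r2_min, a %in% gwas$variant_id,
                  !b %in% gwas$variant_id) |>
    dplyr::left_join(gwas, by = c(a = "variant_id")) |>
    dplyr::transmute(
      variant_id = b,
      risk_allele = dplyr::coalesce(aligned_allele, risk_allele),
      other_allele, odds_ratio, p, locus_id,
      index_variant = a, is_proxy = TRUE,
      orientation_known = !is.na(aligned_allele) | !is.na(risk_allele))
  dplyr::bind_rows(idx, dplyr::distinct(prox, variant_id, index_variant,
                                        .keep_all = TRUE))
}

#' Filter eQTL records for significance and cross-cohort consistency
#'
#' Keeps records with `p < p_max` (strict) and, when required, a direction
#' string that is consistent across all four cohorts (`++++` or `----`).
#'
#' @param records eQTL tibble (`variant_id`, `effect_allele`, `gene`, `z`,
#'   `p`, `cohort_directions`).
#' @param p_max p-value bound (default 0.05).
#' @param require_consistent require `++++`/`----` (default TRUE).
#' @return the retained records.
#' @export
filter_eqtls <- function(records, p_max = 0.05, require_consistent = TRUE) {
  bad <- !grepl("^[+-]{4}$", records$cohort_directions)
  if (any(bad))
    stop("malformed direction string at row ", which(bad)[1], call. = FALSE)
  out <- records |> dplyr::filter(p < p_max)
  if (require_consistent)
    out <- out |> dplyr::filter(cohort_directions %in% c("++++", "----"))
  out
}

#' Classify risk-allele/DEG direction concordance
#'
#' Per (gene, signal): the eQTL Z sign is oriented to the risk allele
#' (flipped when the effect allele differs); a signal is concordant when the
#' oriented sign matches the sign of the gene's T2D-vs-ND log2FC. Signals of
#' one locus hitting the same gene collapse to the max-|z| record. The gene
#' class is `concordant` when all retained signals agree, `discordant` when
#' none do, `mixed` otherwise. Z of exactly zero is uninformative and
#' dropped; genes without a DEG entry are skipped with a warning.
#'
#' @param variants variant tibble from [expand_ld_proxies()] (needs
#'   `variant_id`, `risk_allele`, `locus_id`, `orientation_known`).
#' @param eqtls retained records from [filter_eqtls()].
#' @param degs tibble `gene`, `log2fc`.
#' @return tibble of class `concordance_calls`: `gene`, `class`, `n_signals`,
#'   `deg_log2fc`, `supporting_variants`.
#' @export
classify_concordance <- function(variants, eqtls, degs) {
  joined <- eqtls |>
    dplyr::inner_join(variants |>
                        dplyr::select(variant_id, risk_allele, locus_id,
                                      orientation_known),
                      by = "variant_id") |>
    dplyr::filter(orientation_known, z != 0) |>
    dplyr::mutate(oriented_z = ifelse(effect_allele == risk_allele, z, -z))
  missing <- setdiff(unique(joined$gene), degs$gene)
  if (length(missing))
    warning("gene(s) without DEG entry skipped: ",
            paste(missing, collapse = ", "))
  joined <- joined |>
    dplyr::inner_join(degs, by = "gene") |>
    dplyr::group_by(gene, locus_id) |>
    dplyr::slice_max(abs(z), n = 1, with_ties = FALSE) |>   # locus collapse
    dplyr::ungroup() |>
    dplyr::mutate(concordant = sign(oriented_z) == sign(log2fc))
  out <- joined |>
    dplyr::group_by(gene) |>
    dplyr::summarise(
      class = dplyr::case_when(all(concordant) ~ "concordant",
                               !any(concordant) ~ "discordant",
                               TRUE ~ "mixed"),
      n_signals = dplyr::n(),
      deg_log2fc = log2fc[1],
      supporting_variants = paste(variant_id, collapse = ","),
      .groups = "drop")
  class(out) <- c("concordance_calls", class(out))
  out
}

#' Integrate proteomic and mouse-knockout evidence
#'
#' Orthogonal evidence flags: the protein flag is set when the islet protein
#' fold-change sign matches the DEG sign at protein `p <= 0.05`; the mouse
#' flag when the knockout's glucose-tolerance direction is T2D-consistent
#' for the DEG direction (down-DEG with impaired tolerance, up-DEG with
#' improved). A gene is a candidate when concordant or carrying at least one
#' orthogonal flag; output is ranked by class, flag count and DEG magnitude.
#'
#' @param calls a `concordance_calls` tibble.
#' @param protein tibble `gene`, `log2fc_protein`, `p` (or `NULL`).
#' @param mouse tibble `gene`, `phenotype`, `direction` with direction in
#'   `impaired`/`improved` (or `NULL`).
#' @return tibble with `protein_direction_match`, `mouse_ko_direction_match`,
#'   `candidate`, ranked.
#' @export
integrate_evidence <- function(calls, protein = NULL, mouse = NULL) {
  out <- tibble::as_tibble(calls)
  prot <- if (!is.null(protein)) protein |>
    dplyr::transmute(gene, prot_sign = sign(log2fc_protein),
                     prot_p = p) else
      tibble::tibble(gene = character(), prot_sign = numeric(),
                     prot_p = numeric())
  mo <- if (!is.null(mouse)) mouse |>
    dplyr::transmute(gene, ko_dir = direction) else
      tibble::tibble(gene = character(), ko_dir = character())
  out |>
    dplyr::left_join(prot, by = "gene") |>
    dplyr::left_join(mo, by = "gene") |>
    dplyr::mutate(
      protein_direction_match = !is.na(prot_sign) & prot_p <= 0.05 &
        prot_sign == sign(deg_log2fc),
      mouse_ko_direction_match = !is.na(ko_dir) &
        ((deg_log2fc < 0 & ko_dir == "impaired") |
           (deg_log2fc > 0 & ko_dir == "improved")),
      n_flags = protein_direction_match + mouse_ko_direction_match,
      candidate = class == "concordant" | n_flags >= 1) |>
    dplyr::select(-prot_sign, -prot_p, -ko_dir) |>
    dplyr::arrange(factor(class, levels = c("concordant", "mixed",
                                            "discordant")),
                   dplyr::desc(n_flags), dplyr::desc(abs(deg_log2fc)))
}
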
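# Post-mapping analytics: directional-consistency classes, cell-type
# specificity calls, cross-cell-type effect sharing, and replication.

#' Classify imQTLs by directional consistency with marginal effects
#'
#' An imQTL is `"unknown"` when its marginal mQTL p-value exceeds the
#' threshold (or no marginal record exists), `"consistent"` when the
#' interaction term and the marginal effect share a sign, `"inconsistent"`
#' otherwise. Every imQTL receives exactly one class.
#'
#' @param imqtls Tibble with `variant_id`, `cpg_id`, `cell_type`,
#'   `beta_gxc`, `p_gxc` (e.g. significant leads of an interaction scan).
#' @param marginals Tibble of marginal records with `variant_id`, `cpg_id`,
#'   `beta_main`, `p_main`.
#' @param marginal_p_threshold Marginal significance threshold below which a
#'   marginal effect counts as detectable (default 1e-5).
#' @return The input tibble with `beta_marginal`, `p_marginal` and `class`
#'   columns; per-cell-type summary in [consistency_summary()].
#' @export
classify_directional_consistency <- function(imqtls, marginals,
                                             marginal_p_threshold = 1e-5) {
  out <- imqtls |>
    left_join(select(marginals, "variant_id", "cpg_id",
                     beta_marginal = "beta_main", p_marginal = "p_main"),
              by = c("variant_id", "cpg_id")) |>
    mutate(class = dplyr::case_when(
      is.na(.data$p_marginal) | .data$p_marginal > marginal_p_threshold ~ "unknown",
      sign(.data$beta_marginal) == sign(.data$beta_gxc) ~ "consistent",
      TRUE ~ "inconsistent"))
  if (anyNA(out$p_marginal)) {
    inform(sprintf("%d imQTLs lack a marginal record; classified unknown",
                   sum(is.na(out$p_marginal))))
  }
  out
}

#' Summarize directional-consistency classes per cell type
#'
#' @param classified Output of [classify_directional_consistency()].
#' @return Tibble with per-cell-type counts and the percentage of
#'   directionally consistent imQTLs among all imQTLs of that cell type.
#' @export
consistency_summary <- function(classified) {
  classified |>
    group_by(.data$cell_type) |>
    summarise(n_total = dplyr::n(),
              n_consistent = sum(.data$class == "consistent"),
              n_inconsistent = sum(.data$class == "inconsistent"),
              n_unknown = sum(.data$class == "unknown"),
              pct_consistent = 100 * .data$n_consistent / .data$n_total,
              .groups = "drop")
}

#' Genotype-methylation association within a composition stratum
#'
#' Ordinary least squares of the transformed methylation response on
#' genotype (plus covariates) within the upper or lower half of a cell
#' type's estimated proportion. The two halves partition the samples:
#' values exactly at the median fall in the lower half.
#'
#' @param y Transformed methylation response vector.
#' @param g Genotype dosage vector.
#' @param prop Proportion vector of the stratifying cell type.
#' @param half `"upper"` or `"lower"`.
#' @param covars Optional covariate matrix.
#' @return One-row tibble with `slope`, `se`, `p`, `n`, `half` and
#'   `untestable` (TRUE when the genotype is monomorphic in the stratum or
#'   the stratum has fewer than 10 samples).
#' @export
stratified_association <- function(y, g, prop, half = c("upper", "lower"),
                                   covars = NULL) {
  half <- match.arg(half)
  sel <- if (half == "upper") prop > median(prop) else prop <= median(prop)
  n <- sum(sel)
  if (n < 10 || var(g[sel]) == 0) {
    return(tibble(slope = NA_real_, se = NA_real_, p = NA_real_, n = n,
                  half = half, untestable = TRUE))
  }
  cv <- if (is.null(covars)) NULL else covars[sel, , drop = FALSE]
  fit <- fit_interaction_model(y[sel], g[sel], covars = cv,
                               interaction = FALSE)
  tibble(slope = fit$beta_main, se = fit$se_main, p = fit$p_main, n = n,
         half = half, untestable = FALSE)
}

#' Call a cell-type-specific imQTL
#'
#' Two criteria, both required. Criterion 1 (interaction pattern): the
#' modeled cell type's interaction term has the opposite sign to every
#' other cell type's, or no other cell type has a nominally significant
#' interaction (p < 0.05). Criterion 2 (stratified associations): the
#' genotype-methylation association is nominally significant in the upper
#' half of the modeled cell type's proportion, and in every other cell
#' type's upper half the association is either non-significant or points in
#' the opposite direction to the modeled type's. Strata in which the
#' genotype is untestable count as non-significant.
#'
#' @param cell_type The modeled cell type.
#' @param interaction_fits Tibble with one row per retained cell type:
#'   `cell_type`, `beta_gxc`, `p_gxc` for the same variant-CpG pair.
#' @param stratified_fits Tibble with one row per retained cell type:
#'   `cell_type`, `slope`, `p` (upper-half associations; see
#'   [stratified_association()]), optional `untestable`.
#' @return List with `specific` (logical), `criterion1`, `criterion2` and an
#'   `evidence` tibble.
#' @export
call_cell_type_specific <- function(cell_type, interaction_fits,
                                    stratified_fits) {
  assert_that(nrow(interaction_fits) >= 2,
              "need interaction fits for at least 2 cell types")
  tgt <- filter(interaction_fits, .data$cell_type == !!cell_type)
  oth <- filter(interaction_fits, .data$cell_type != !!cell_type)
  assert_that(nrow(tgt) == 1, "exactly one interaction fit for the modeled type required")
  crit1 <- all(sign(oth$beta_gxc) != sign(tgt$beta_gxc)) ||
    all(oth$p_gxc >= 0.05)
  s_tgt <- filter(stratified_fits, .data$cell_type == !!cell_type)
  s_oth <- filter(stratified_fits, .data$cell_type != !!cell_type)
  assert_that(nrow(s_tgt) == 1, "exactly one stratified fit for the modeled type required")
  if (!"untestable" %in% names(stratified_fits)) {
    s_tgt$untestable <- FALSE
    s_oth$untestable <- is.na(s_oth$p)
  }
  crit2 <- !isTRUE(s_tgt$untestable) && isTRUE(s_tgt$p < 0.05) &&
    all(s_oth$untestable | s_oth$p >= 0.05 |
          sign(s_oth$slope) != sign(s_tgt$slope))
  list(specific = crit1 && crit2, criterion1 = crit1, criterion2 = crit2,
       evidence = list(interaction = interaction_fits,
                       stratified = stratified_fits))
}

#' Cross-cell-type sharing of interaction effects
#'
#' Entry (a, b) is the fraction of the tissue's imQTLs (the union of lead
#' pairs discovered in any cell type) for which cell type b's interaction
#' term has the same sign as cell type a's and b's p-value is below 0.05.
#' Rows index the reference cell type a; the matrix need not be symmetric
#' and its diagonal is 1 by definition. Pairs untestable in b are excluded
#' from that entry's denominator and counted.
#'
#' @param fits Tibble with `pair_id` (one value per imQTL), `cell_type`,
#'   `beta_gxc`, `p_gxc`, covering the tissue's imQTLs refit in every
#'   retained cell type; missing rows mark untestable combinations.
#' @return List of class `imqtl_sharing`: `sharing` (K x K matrix),
#'   `order` (average-linkage dendrogram order on one minus the
#'   symmetrized sharing), `n_pairs`, `n_untestable` (matrix of excluded
#'   counts).
#' @export
effect_sharing_matrix <- function(fits) {
  cells <- unique(fits$cell_type)
  assert_that(length(cells) >= 2, "need at least 2 cell types")
  pairs <- unique(fits$pair_id)
  assert_that(length(pairs) >= 1, "zero imQTLs: nothing to share")
  k <- length(cells)
  wide_b <- matrix(NA_real_, length(pairs), k,
                   dimnames = list(pairs, cells))
  wide_p <- wide_b
  for (r in seq_len(nrow(fits))) {
    wide_b[fits$pair_id[r], fits$cell_type[r]] <- fits$beta_gxc[r]
    wide_p[fits$pair_id[r], fits$cell_type[r]] <- fits$p_gxc[r]
  }
  sharing <- matrix(1, k, k, dimnames = list(cells, cells))
  untest <- matrix(0L, k, k, dimnames = list(cells, cells))
  for (a in cells) for (b in setdiff(cells, a)) {
    ok <- !is.na(wide_b[, a]) & !is.na(wide_b[, b])
    untest[a, b] <- sum(!ok)
    shared <- sign(wide_b[ok, b]) == sign(wide_b[ok, a]) & wide_p[ok, b] < 0.05
    sharing[a, b] <- if (any(ok)) mean(shared) else NA_real_
  }
  sym <- 1 - (sharing + t(sharing)) / 2
  ord <- if (k > 2) stats::hclust(stats::as.dist(sym), method = "average")$order
         else seq_len(k)
  structure(list(sharing = sharing, order = cells[ord],
                 n_pairs = length(pairs), n_untestable = untest),
            class = "imqtl_sharing")
}

#' Replicate discovery imQTLs in an independent study
#'
#' A discovery imQTL is validated when the replication interaction term is
#' nominally significant (p < 0.05) with the same sign. Alleles are
#' harmonized on (chrom, pos, ref, alt) when allele columns are present:
#' a ref/alt swap flips the replication sign; any other allele mismatch is
#' an error (strand flips unsupported). Pairs untestable in replication are
#' excluded from the denominator and counted separately.
#'
#' @param discovery Tibble with `variant_id`, `cpg_id`, `cell_type`,
#'   `beta_gxc` (and optionally `chrom`, `pos`, `ref`, `alt`).
#' @param replication Tibble with the same keys plus `beta_gxc`, `p_gxc`.
#' @return List with `report` (per-cell-type validation fractions),
#'   `n_untestable`, `r_squared` (squared correlation of discovery and
#'   replication interaction estimates) and `data` (the joined table).
#' @export
replicate_imqtls <- function(discovery, replication) {
  harmonize <- all(c("ref", "alt") %in% names(discovery)) &&
    all(c("ref", "alt") %in% names(replication))
  keys <- c("variant_id", "cpg_id", "cell_type")
  rep2 <- replication |>
    select(dplyr::all_of(c(keys,
                           if (harmonize) c("ref", "alt") else NULL)),
           beta_rep = "beta_gxc", p_rep = "p_gxc")
  if (harmonize) rep2 <- rename(rep2, ref_rep = "ref", alt_rep = "alt")
  joined <- left_join(discovery, rep2, by = keys)
  if (harmonize) {
    same <- joined$ref == joined$ref_rep & joined$alt == joined$alt_rep
    swap <- joined$ref == joined$alt_rep & joined$alt == joined$ref_rep
    bad <- !is.na(joined$beta_rep) & !(same | swap)
    if (any(bad)) {
      abort(sprintf("%d pairs have non-matching alleles (strand flips unsupported)",
                    sum(bad)))
    }
    joined$beta_rep <- ifelse(swap, -joined$beta_rep, joined$beta_rep)
  }
  testable <- !is.na(joined$beta_rep)
  joined$validated <- testable & joined$p_rep < 0.05 &
    sign(joined$beta_rep) == sign(joined$beta_gxc)
  report <- joined |>
    filter(testable) |>
    group_by(.data$cell_type) |>
    summarise(n_testable = dplyr::n(), n_validated = sum(.data$validated),
              fraction_validated = mean(.data$validated), .groups = "drop")
  r2 <- if (sum(testable) >= 3) {
    cor(joined$beta_gxc[testable], joined$beta_rep[testable])^2
  } else NA_real_
  list(report = report, n_untestable = sum(!testable), r_squared = r2,
       data = joined)
}
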
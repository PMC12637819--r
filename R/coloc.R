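# Enumeration-based colocalization of two summary-statistic tracks under
# the single-causal-variant-per-trait assumption, via Wakefield approximate
# Bayes factors, plus the prior-derivation calculator.

#' Wakefield log approximate Bayes factor
#'
#' With `z = effect / se`, `V = se^2` and `W` the prior effect variance,
#' `log ABF = 0.5 log(V / (V + W)) + 0.5 z^2 W / (V + W)`, the log marginal
#' likelihood ratio of an associated versus null variant under a Gaussian
#' effect prior.
#'
#' @param effect Effect estimate(s).
#' @param se Standard error(s), positive.
#' @param sd_prior Prior effect SD (sqrt of W); 0.15 is the conventional
#'   default for quantitative traits, 0.2 for case-control.
#' @return Log ABF, vectorized.
#' @export
wakefield_abf <- function(effect, se, sd_prior = 0.15) {
  assert_that(all(is.finite(effect)) && all(is.finite(se)) &&
                is.finite(sd_prior), "non-finite inputs")
  assert_that(all(se > 0), "standard errors must be positive")
  assert_that(sd_prior > 0, "prior SD must be positive")
  v <- se^2
  w <- sd_prior^2
  z2 <- (effect / se)^2
  0.5 * log(v / (v + w)) + 0.5 * z2 * w / (v + w)
}

#' Colocalization priors
#'
#' @param p1,p2 Per-variant prior probabilities of association with trait 1
#'   only / trait 2 only.
#' @param p12 Per-variant prior probability of association with both.
#' @return List of class `coloc_priors`. All three must be positive and sum
#'   to less than 1.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  assert_that(p1 > 0 && p2 > 0 && p12 > 0, "priors must be positive")
  assert_that(p1 + p2 + p12 < 1, "priors must sum to less than 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Derive colocalization priors from genome-wide variant counts
#'
#' Given `n_total` common variants of which `n_trait1` regulate trait 1,
#' `n_trait2` regulate trait 2, and `n_shared` regulate both:
#' `p1 = (n_trait1 - n_shared) / n_total`,
#' `p2 = (n_trait2 - n_shared) / n_total`, `p12 = n_shared / n_total`.
#'
#' @param n_total Total number of common variants.
#' @param n_trait1,n_trait2 Variants regulating each trait.
#' @param n_shared Variants regulating both (must be positive and at most
#'   the smaller trait count).
#' @return A [coloc_priors()] object.
#' @export
derive_priors <- function(n_total, n_trait1, n_trait2, n_shared) {
  assert_that(n_shared > 0, "n_shared must be positive (priors must be > 0)")
  assert_that(n_shared <= min(n_trait1, n_trait2),
              "n_shared cannot exceed either trait's variant count")
  assert_that(n_total > n_trait1 + n_trait2,
              "n_total must exceed the summed trait counts")
  coloc_priors(p1 = (n_trait1 - n_shared) / n_total,
               p2 = (n_trait2 - n_shared) / n_total,
               p12 = n_shared / n_total)
}

harmonize_stats <- function(stats1, stats2) {
  have_alleles <- all(c("ref", "alt") %in% names(stats1)) &&
    all(c("ref", "alt") %in% names(stats2))
  s2 <- stats2
  names(s2) <- paste0(names(s2), "_2")
  joined <- dplyr::inner_join(stats1, s2,
                              by = c(variant_id = "variant_id_2"))
  dropped <- character()
  if (have_alleles && nrow(joined) > 0) {
    same <- joined$ref == joined$ref_2 & joined$alt == joined$alt_2
    swap <- joined$ref == joined$alt_2 & joined$alt == joined$ref_2
    joined$beta_2[swap] <- -joined$beta_2[swap]
    dropped <- joined$variant_id[!(same | swap)]
    joined <- joined[same | swap, , drop = FALSE]
  }
  list(joined = joined, dropped = dropped)
}

#' Enumerate colocalization posteriors for one locus
#'
#' Under the assumption of at most one causal variant per trait, sums
#' per-variant Wakefield ABFs over the five causal configurations —
#' neither trait associated (H0), trait 1 only (H1), trait 2 only (H2),
#' two distinct causal variants (H3), one shared causal variant (H4) —
#' weighting by the per-variant priors, and normalizes to posterior
#' probabilities PP0-PP4. All sums run in log space.
#'
#' @param stats1,stats2 Summary-stat tibbles with `variant_id`, `beta`,
#'   `se` (and optionally `ref`/`alt` for allele harmonization; unresolvable
#'   alleles are dropped with a message).
#' @param priors A [coloc_priors()] object.
#' @param sd_prior1,sd_prior2 ABF prior effect SDs per trait (0.15
#'   quantitative, 0.2 case-control).
#' @return One-row tibble of class `imqtl_coloc`: `pp0`..`pp4`,
#'   `n_variants`.
#' @export
coloc_enumerate <- function(stats1, stats2, priors = coloc_priors(),
                            sd_prior1 = 0.15, sd_prior2 = 0.15) {
  h <- harmonize_stats(stats1, stats2)
  if (length(h$dropped) > 0) {
    inform(sprintf("dropped %d variants with unresolvable alleles: %s",
                   length(h$dropped),
                   paste(head(h$dropped, 5), collapse = ", ")))
  }
  j <- h$joined
  if (nrow(j) == 0) {
    abort("zero shared variants after harmonization")
  }
  l1 <- wakefield_abf(j$beta, j$se, sd_prior1)
  l2 <- wakefield_abf(j$beta_2, j$se_2, sd_prior2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lh <- c(h0 = 0,
          h1 = log(priors$p1) + s1,
          h2 = log(priors$p2) + s2,
          h3 = log(priors$p1) + log(priors$p2) + logdiffexp(s1 + s2, s12),
          h4 = log(priors$p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  out <- tibble(pp0 = pp[["h0"]], pp1 = pp[["h1"]], pp2 = pp[["h2"]],
                pp3 = pp[["h3"]], pp4 = pp[["h4"]], n_variants = nrow(j))
  class(out) <- c("imqtl_coloc", class(out))
  out
}

#' Call colocalized loci and flag top partners
#'
#' A locus pair is called colocalized when PP4 strictly exceeds the
#' threshold; per CpG, the partner with the highest PP4 among called pairs
#' is flagged as the top colocalization.
#'
#' @param results Tibble with `cpg_id`, `partner_id`, `pp4` and optionally
#'   `partner_type` (e.g. "eqtl"/"gwas").
#' @param threshold PP4 call threshold (default 0.5, strict >).
#' @return The input with `colocalized` and `top_partner` flags; when
#'   `partner_type` is present, a per-CpG cross-tabulation of partner types
#'   in attribute `"cross_tab"`.
#' @export
classify_colocalized <- function(results, threshold = 0.5) {
  out <- results |>
    mutate(colocalized = .data$pp4 > threshold) |>
    group_by(.data$cpg_id) |>
    mutate(top_partner = .data$colocalized &
             .data$pp4 == max(.data$pp4[.data$colocalized], -Inf)) |>
    ungroup()
  if ("partner_type" %in% names(results)) {
    tab <- out |>
      filter(.data$colocalized) |>
      distinct(.data$cpg_id, .data$partner_type) |>
      group_by(.data$cpg_id) |>
      summarise(types = paste(sort(unique(.data$partner_type)),
                              collapse = "+"), .groups = "drop") |>
      count(.data$types)
    attr(out, "cross_tab") <- tab
  }
  out
}
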
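# Interaction and marginal cis-mQTL mapping.
#
# The interaction model regresses transformed methylation on genotype, the
# rank-transformed cell-type proportion, their product, and covariates:
#
#   y_i = b0 + b1 G_i + b2 C_i + b3 G_i C_i + covariates + e_i
#
# with y the rank-inverse-normal transformed M-value, C the rank-inverse-
# normal transformed estimated proportion of the modeled cell type, and the
# interaction regressor the product of the raw dosage with the transformed
# proportion. b3 is the tested interaction term; b1 is the "main effect".
# Dropping C and the product gives the marginal cis-mQTL model whose genotype
# coefficient is the "marginal effect". P-values use the t distribution with
# residual degrees of freedom n - p.

#' Stratified minor-allele-frequency filter
#'
#' Samples are split at the median of the modeled cell type's estimated
#' proportion (values exactly at the median go to the lower half); a variant
#' is kept only if its MAF exceeds `maf_min` in both halves. This guards
#' interaction tests against allele-frequency artefacts confined to one end
#' of the composition distribution.
#'
#' @param dosage Sample x variant dosage matrix.
#' @param prop Numeric vector of the cell type's proportions, aligned with
#'   rows of `dosage`.
#' @param maf_min MAF threshold (default 0.1, strict >).
#' @return Named logical keep-mask over variants.
#' @export
stratified_maf_filter <- function(dosage, prop, maf_min = 0.1) {
  assert_that(nrow(dosage) >= 4, "need at least 4 samples to stratify")
  upper <- prop > median(prop)
  half_maf <- function(rows) {
    f <- colMeans(dosage[rows, , drop = FALSE]) / 2
    pmin(f, 1 - f)
  }
  keep <- half_maf(upper) > maf_min & half_maf(!upper) > maf_min
  names(keep) <- colnames(dosage)
  keep
}

#' Fit one interaction model (reference path)
#'
#' Straightforward [lm()] fit of the interaction model for a single
#' variant-CpG pair. This is the plain reference implementation; the scan
#' engine used by [map_interaction_mqtls()] is checked against it.
#'
#' @param y Transformed methylation response vector.
#' @param g Genotype dosage vector.
#' @param c_int Rank-transformed cell-type proportion vector.
#' @param covars Optional numeric matrix of covariates (no intercept).
#' @param interaction If FALSE, fit the marginal model (no `C`, no product).
#' @return One-row tibble with estimates, SEs and p-values for the main
#'   genotype term and, for interaction fits, the cell and interaction
#'   terms, plus `n` and residual `df`.
#' @export
fit_interaction_model <- function(y, g, c_int = NULL, covars = NULL,
                                  interaction = TRUE) {
  df0 <- data.frame(y = y, g = g)
  if (interaction) {
    assert_that(!is.null(c_int), "interaction fit needs the proportion vector")
    df0$c_int <- c_int
    form <- y ~ g + c_int + g:c_int
  } else {
    form <- y ~ g
  }
  if (!is.null(covars)) {
    covars <- as.matrix(covars)
    keep <- apply(covars, 2, var) > 0
    if (any(keep)) {
      df0 <- cbind(df0, covars[, keep, drop = FALSE])
      form <- stats::update.formula(
        form, paste("~ . +", paste(colnames(covars)[keep], collapse = " + ")))
    }
  }
  fit <- lm(form, data = df0)
  sm <- summary(fit)$coefficients
  if (qr(fit)$rank < length(coef(fit))) {
    abort("rank-deficient design after zero-variance removal")
  }
  grab <- function(term) {
    if (!term %in% rownames(sm)) return(c(NA, NA, NA))
    unname(sm[term, c(1, 2, 4)])
  }
  main <- grab("g"); cell <- grab("c_int"); gxc <- grab("g:c_int")
  tibble(beta_main = main[1], se_main = main[2], p_main = main[3],
         beta_cell = cell[1], se_cell = cell[2], p_cell = cell[3],
         beta_gxc = gxc[1], se_gxc = gxc[2], p_gxc = gxc[3],
         n = length(y), df = fit$df.residual)
}

#' Effective number of independent tests
#'
#' Eigen-decomposes the correlation matrix of the tested variants and
#' returns the smallest number of leading eigenvalues capturing at least
#' `var_explained` of their sum. Perfectly correlated variants therefore
#' count once; independent variants count nearly fully.
#'
#' @param dosage Sample x variant dosage submatrix of the variants tested
#'   for one CpG.
#' @param var_explained Fraction of total eigenvalue mass to capture
#'   (default 0.995).
#' @return Integer effective number of tests, between 1 and the number of
#'   variants.
#' @export
emt_estimate <- function(dosage, var_explained = 0.995) {
  dosage <- as.matrix(dosage)
  assert_that(ncol(dosage) >= 1, "need at least one variant")
  v <- apply(dosage, 2, var)
  if (any(v == 0)) {
    warn(sprintf("excluding %d constant variant column(s) from EMT estimate",
                 sum(v == 0)))
    dosage <- dosage[, v > 0, drop = FALSE]
    if (ncol(dosage) == 0) return(1L)
  }
  if (ncol(dosage) == 1) return(1L)
  ev <- eigen(cor(dosage), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  as.integer(which(cumsum(ev) >= var_explained * sum(ev))[1])
}

# Vectorized cis scan: for each variant the design matrix is fixed across
# CpGs, so one Cholesky factorization serves every CpG in the variant's
# window; per-pair work reduces to cross-products. Checked against
# fit_interaction_model() to 1e-8 relative error.
scan_engine <- function(dosage, variants, Y, cpgs, covars_mat, c_int,
                        interaction, mask, cis_window) {
  n <- nrow(dosage)
  yty <- rowSums(Y^2)
  base <- if (interaction) {
    cbind(intercept = rep(1, n), g = numeric(n), c_int = c_int, gxc = numeric(n))
  } else {
    cbind(intercept = rep(1, n), g = numeric(n))
  }
  if (!is.null(covars_mat) && ncol(covars_mat) > 0) {
    base <- cbind(base, covars_mat)
  }
  p <- ncol(base)
  gi <- 2L
  ci <- if (interaction) 3L else NA_integer_
  xi <- if (interaction) 4L else NA_integer_
  rows <- vector("list", nrow(variants))
  for (v in seq_len(nrow(variants))) {
    if (!mask[v]) next
    in_cis <- cpgs$chrom == variants$chrom[v] &
      abs(cpgs$pos - variants$pos[v]) <= cis_window
    if (!any(in_cis)) next
    X <- base
    X[, gi] <- dosage[, v]
    if (interaction) X[, xi] <- dosage[, v] * c_int
    xtx <- crossprod(X)
    R <- tryCatch(chol(xtx), error = function(e) NULL)
    if (is.null(R)) next # rank-deficient design for this variant
    inv <- chol2inv(R)
    J <- which(in_cis)
    B <- Y[J, , drop = FALSE] %*% X      # |J| x p cross-products X'y
    Beta <- B %*% inv                    # |J| x p coefficient estimates
    rss <- pmax(yty[J] - rowSums(Beta * B), 0)
    dfree <- n - p
    sigma2 <- rss / dfree
    se <- sqrt(outer(sigma2, diag(inv)))
    tval <- Beta / se
    pval <- 2 * pt(abs(tval), dfree, lower.tail = FALSE)
    rows[[v]] <- tibble(
      variant_id = variants$variant_id[v], chrom = variants$chrom[v],
      pos = variants$pos[v], cpg_id = cpgs$cpg_id[J], cpg_pos = cpgs$pos[J],
      n = n,
      beta_main = unname(Beta[, gi]), se_main = unname(se[, gi]),
      p_main = unname(pval[, gi]),
      beta_cell = if (interaction) unname(Beta[, ci]) else NA_real_,
      se_cell = if (interaction) unname(se[, ci]) else NA_real_,
      p_cell = if (interaction) unname(pval[, ci]) else NA_real_,
      beta_gxc = if (interaction) unname(Beta[, xi]) else NA_real_,
      se_gxc = if (interaction) unname(se[, xi]) else NA_real_,
      p_gxc = if (interaction) unname(pval[, xi]) else NA_real_,
      distance = variants$pos[v] - cpgs$pos[J])
  }
  bind_rows(rows)
}

align_study <- function(genotypes, meth, proportions, covariates) {
  ids <- rownames(genotypes$dosage)
  assert_that(setequal(ids, colnames(meth)) &&
                setequal(ids, proportions$sample_id),
              "sample ids of genotypes, methylation and proportions must match")
  meth <- meth[, ids, drop = FALSE]
  proportions <- proportions[match(ids, proportions$sample_id), ]
  if (!is.null(covariates)) {
    assert_that(setequal(ids, covariates$sample_id),
                "covariate sample ids must match genotypes")
    covariates <- covariates[match(ids, covariates$sample_id), ]
  }
  list(meth = meth, proportions = proportions, covariates = covariates)
}

covariate_matrix <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  m <- as.matrix(covariates[setdiff(names(covariates), "sample_id")])
  m[, apply(m, 2, var) > 0, drop = FALSE]
}

transform_meth <- function(beta, transform) {
  if (transform == "none") return(beta)
  m <- beta_to_mvalue(beta)
  t(apply(m, 1, rank_inverse_normal))
}

#' Map cell type-interaction cis-mQTLs
#'
#' For each CpG, every variant within the cis window that passes the
#' stratified MAF filter is tested with the interaction model. Per CpG the
#' minimum interaction p-value is adjusted by the effective number of tests
#' (`p_emt = min(1, p_min * M_eff)`); across CpGs a Bonferroni correction by
#' the number of CpGs tested gives `p_bonf`. The lead pair per CpG is the
#' variant with the smallest interaction p (ties broken by smaller
#' variant-CpG distance, then lexicographic variant id); an imQTL is a lead
#' pair with `p_bonf < alpha`.
#'
#' @param genotypes `imqtl_geno` object.
#' @param meth CpG x sample methylation matrix (beta scale unless
#'   `transform = "none"`, in which case it is used as the response
#'   directly).
#' @param cpgs Tibble with `cpg_id`, `chrom`, `pos`.
#' @param proportions Proportion tibble (sample_id + cell columns).
#' @param cell_type Name of the modeled cell type.
#' @param covariates Optional covariate tibble (`sample_id` + numeric
#'   columns such as age, sex, PCs).
#' @param cis_window Window half-width in bp (default 500 kb, inclusive).
#' @param maf_min Stratified MAF threshold (default 0.1).
#' @param transform `"int_mvalue"` (rank-inverse-normal of M-values, the
#'   default) or `"none"`.
#' @param emt Use the eigenvalue-based effective number of tests (default);
#'   if FALSE, plain Bonferroni by the per-CpG variant count.
#' @param alpha Significance level on `p_bonf` (default 0.05).
#' @return Object of class `imqtl_scan`: list with `associations` (all pair
#'   fits), `leads` (per-CpG lead records with `p_min`, `m_eff`, `p_emt`,
#'   `p_bonf`, `significant`), `skipped` (CpGs without testable variants)
#'   and `meta`.
#' @export
map_interaction_mqtls <- function(genotypes, meth, cpgs, proportions,
                                  cell_type, covariates = NULL,
                                  cis_window = 5e5, maf_min = 0.1,
                                  transform = c("int_mvalue", "none"),
                                  emt = TRUE, alpha = 0.05) {
  transform <- match.arg(transform)
  al <- align_study(genotypes, meth, proportions, covariates)
  assert_that(cell_type %in% names(al$proportions),
              sprintf("cell type '%s' not found in proportions", cell_type))
  prop <- al$proportions[[cell_type]]
  c_int <- rank_inverse_normal(prop)
  mask <- stratified_maf_filter(genotypes$dosage, prop, maf_min)
  Y <- transform_meth(al$meth, transform)
  covm <- covariate_matrix(al$covariates)
  assoc <- scan_engine(genotypes$dosage, genotypes$variants, Y, cpgs, covm,
                       c_int, TRUE, mask, cis_window) |>
    mutate(cell_type = cell_type, .before = "n")
  finalize_scan(assoc, cpgs, genotypes, mask, cis_window, emt, alpha,
                cell_type, term = "p_gxc")
}

#' Map marginal cis-mQTLs
#'
#' Identical scan without the cell-proportion and interaction terms; the
#' genotype coefficient is the marginal effect and the MAF filter is the
#' plain (unstratified) `MAF > maf_min` cutoff.
#'
#' @inheritParams map_interaction_mqtls
#' @return `imqtl_scan` object; marginal records carry the genotype term
#'   only.
#' @export
map_marginal_mqtls <- function(genotypes, meth, cpgs, proportions = NULL,
                               covariates = NULL, cis_window = 5e5,
                               maf_min = 0.1,
                               transform = c("int_mvalue", "none"),
                               emt = TRUE, alpha = 0.05) {
  transform <- match.arg(transform)
  ids <- rownames(genotypes$dosage)
  props <- proportions %||% tibble(sample_id = ids)
  al <- align_study(genotypes, meth, props, covariates)
  f <- colMeans(genotypes$dosage) / 2
  mask <- pmin(f, 1 - f) > maf_min
  Y <- transform_meth(al$meth, transform)
  covm <- covariate_matrix(al$covariates)
  assoc <- scan_engine(genotypes$dosage, genotypes$variants, Y, cpgs, covm,
                       NULL, FALSE, mask, cis_window) |>
    mutate(cell_type = "marginal", .before = "n")
  finalize_scan(assoc, cpgs, genotypes, mask, cis_window, emt, alpha,
                "marginal", term = "p_main")
}

finalize_scan <- function(assoc, cpgs, genotypes, mask, cis_window, emt,
                          alpha, cell_type, term) {
  tested_cpgs <- unique(assoc$cpg_id)
  skipped <- tibble(cpg_id = setdiff(cpgs$cpg_id, tested_cpgs),
                    reason = "no testable cis variants")
  if (nrow(assoc) == 0) {
    return(structure(list(associations = assoc, leads = assoc,
                          skipped = skipped,
                          meta = list(cell_type = cell_type, n_cpgs_tested = 0,
                                      alpha = alpha, term = term)),
                     class = "imqtl_scan"))
  }
  n_tested <- length(tested_cpgs)
  leads <- assoc |>
    group_by(.data$cpg_id) |>
    arrange(.data[[term]], abs(.data$distance), .data$variant_id,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  m_eff <- vapply(leads$cpg_id, function(cg) {
    cpos <- cpgs$pos[match(cg, cpgs$cpg_id)]
    cchr <- cpgs$chrom[match(cg, cpgs$cpg_id)]
    vv <- which(mask & genotypes$variants$chrom == cchr &
                  abs(genotypes$variants$pos - cpos) <= cis_window)
    if (emt) emt_estimate(genotypes$dosage[, vv, drop = FALSE])
    else length(vv)
  }, integer(1))
  p_min <- assoc |>
    group_by(.data$cpg_id) |>
    summarise(p_min = min(.data[[term]]), .groups = "drop")
  leads <- leads |>
    left_join(p_min, by = "cpg_id") |>
    mutate(m_eff = as.integer(m_eff),
           p_emt = pmin(1, .data$p_min * .data$m_eff),
           p_bonf = pmin(1, .data$p_emt * n_tested),
           significant = .data$p_bonf < alpha)
  structure(list(associations = assoc, leads = leads, skipped = skipped,
                 meta = list(cell_type = cell_type, n_cpgs_tested = n_tested,
                             alpha = alpha, term = term)),
            class = "imqtl_scan")
}

#' Scan for secondary interaction signals conditional on a lead variant
#'
#' Every variant within the cis window of the lead variant (other than the
#' lead itself and any candidate perfectly correlated with it) is refit with
#' the lead variant's genotype and its interaction added as covariates;
#' candidates with conditional interaction p below `p_threshold` are
#' reported.
#'
#' @param genotypes `imqtl_geno` object.
#' @param meth CpG x sample methylation matrix (see
#'   [map_interaction_mqtls()]).
#' @param cpgs CpG tibble.
#' @param proportions,cell_type,covariates As in [map_interaction_mqtls()].
#' @param cpg_id CpG of the lead pair.
#' @param lead_variant Lead variant id.
#' @param cis_window Window around the lead variant (default 500 kb).
#' @param maf_min Stratified MAF threshold.
#' @param p_threshold Conditional significance threshold (default 1e-5).
#' @param transform Response transform, as in [map_interaction_mqtls()].
#' @return Tibble of candidate secondary signals with conditional interaction
#'   estimates; skipped collinear candidates are listed in attribute
#'   `"skipped"`.
#' @export
conditional_secondary_scan <- function(genotypes, meth, cpgs, proportions,
                                       cell_type, cpg_id, lead_variant,
                                       covariates = NULL, cis_window = 5e5,
                                       maf_min = 0.1, p_threshold = 1e-5,
                                       transform = c("int_mvalue", "none")) {
  transform <- match.arg(transform)
  al <- align_study(genotypes, meth, proportions, covariates)
  prop <- al$proportions[[cell_type]]
  c_int <- rank_inverse_normal(prop)
  mask <- stratified_maf_filter(genotypes$dosage, prop, maf_min)
  Y <- transform_meth(al$meth, transform)
  y <- Y[cpg_id, ]
  covm <- covariate_matrix(al$covariates)
  li <- match(lead_variant, genotypes$variants$variant_id)
  assert_that(!is.na(li), "lead variant not found")
  g_lead <- genotypes$dosage[, li]
  near <- which(mask &
                  genotypes$variants$chrom == genotypes$variants$chrom[li] &
                  abs(genotypes$variants$pos - genotypes$variants$pos[li]) <=
                    cis_window)
  near <- setdiff(near, li)
  skipped <- character()
  out <- list()
  for (v in near) {
    g <- genotypes$dosage[, v]
    r <- suppressWarnings(cor(g, g_lead))
    if (is.finite(r) && r^2 >= 1 - 1e-12) {
      skipped <- c(skipped, genotypes$variants$variant_id[v])
      next
    }
    lead_cov <- cbind(g_lead = g_lead, gxc_lead = g_lead * c_int)
    cv <- if (is.null(covm)) lead_cov else cbind(covm, lead_cov)
    fit <- fit_interaction_model(y, g, c_int, cv)
    out[[length(out) + 1]] <- mutate(fit,
                                     variant_id = genotypes$variants$variant_id[v],
                                     .before = 1)
  }
  res <- bind_rows(out)
  res <- if (nrow(res) > 0) filter(res, .data$p_gxc < p_threshold) else res
  attr(res, "skipped") <- skipped
  res
}

#' Count CpGs regulated by one variant (pleiotropy)
#'
#' @param variant Variant id.
#' @param associations Association tibble (e.g. from an `imqtl_scan`).
#' @param p_threshold Interaction p-value threshold (default 1e-4).
#' @return Number of distinct CpGs with interaction p below the threshold
#'   for that variant.
#' @export
pleiotropy_count <- function(variant, associations, p_threshold = 1e-4) {
  associations |>
    filter(.data$variant_id == variant, .data$p_gxc < p_threshold) |>
    distinct(.data$cpg_id) |>
    nrow()
}
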
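# Synthetic-data generators.
#
# Every downstream stage of the pipeline (deconvolution, interaction mapping,
# classification, colocalization) is exercised on data produced here, so the
# generators carry the statistical structure the analysis assumes: Hardy-
# Weinberg genotypes, Dirichlet cell-type compositions, bulk methylation as a
# proportion-weighted mixture of per-cell-type methylomes with planted
# cell-type-specific genetic effects, and sorted-cell reference profiles with
# planted cell-type-discriminating hypomethylation.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the bulk-methylation generative
#' model. Defaults describe a generic solid tissue with four deconvolutable
#' cell types (a dominant epithelial compartment plus fibroblast, endothelial
#' and immune components) and post-normalization beta-scale noise.
#'
#' @param n_samples Number of individuals.
#' @param n_variants Number of cis variants.
#' @param n_cpgs Number of CpG sites.
#' @param maf_range Range of minor allele frequencies, within (0, 0.5].
#' @param cell_types Character vector of cell-type names (K >= 2).
#' @param dirichlet_alpha Positive Dirichlet concentration per cell type;
#'   controls both mean composition and its between-individual variance.
#' @param effect_table Tibble of planted genetic effects with columns
#'   `cpg_index`, `variant_index`, `cell_type`, `effect` (beta-scale slope per
#'   dosage unit, acting only within the named cell type).
#' @param noise_sd Beta-scale residual standard deviation.
#' @param beta_clip_eps Clipping bound keeping beta in (eps, 1 - eps) so that
#'   M-values stay finite.
#' @param baseline_range Range of the per-CpG grand-mean methylation level.
#' @param celltype_baseline_sd SD of per-cell-type deviations around the CpG
#'   grand mean; nonzero values create cell-type differentially methylated
#'   sites the way real tissue does.
#' @param age_effect,sex_effect Optional beta-scale covariate effects shared
#'   by all CpGs (0 by default: covariates exercise the model plumbing
#'   without biasing effect recovery).
#' @param seed Integer master seed; child seeds are derived per operation.
#' @return A validated list of class `imqtl_config`.
#' @export
simulation_config <- function(n_samples = 200,
                              n_variants = 50,
                              n_cpgs = 20,
                              maf_range = c(0.1, 0.5),
                              cell_types = c("epithelial", "fibroblast",
                                             "endothelial", "immune"),
                              dirichlet_alpha = c(5, 2, 1, 2),
                              effect_table = NULL,
                              noise_sd = 0.05,
                              beta_clip_eps = 1e-3,
                              baseline_range = c(0.2, 0.8),
                              celltype_baseline_sd = 0.1,
                              age_effect = 0,
                              sex_effect = 0,
                              seed = 1L) {
  if (is.null(effect_table)) {
    effect_table <- tibble(cpg_index = integer(), variant_index = integer(),
                           cell_type = character(), effect = numeric())
  }
  cfg <- list(n_samples = n_samples, n_variants = n_variants, n_cpgs = n_cpgs,
              maf_range = maf_range, cell_types = cell_types,
              dirichlet_alpha = dirichlet_alpha,
              effect_table = as_tibble(effect_table), noise_sd = noise_sd,
              beta_clip_eps = beta_clip_eps, baseline_range = baseline_range,
              celltype_baseline_sd = celltype_baseline_sd,
              age_effect = age_effect, sex_effect = sex_effect,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "imqtl_config")
}

validate_config <- function(cfg) {
  assert_that(cfg$n_samples >= 2, "n_samples must be at least 2")
  assert_that(length(cfg$cell_types) >= 2, "at least two cell types required")
  assert_that(length(cfg$dirichlet_alpha) == length(cfg$cell_types),
              "dirichlet_alpha must have one entry per cell type")
  assert_that(all(cfg$dirichlet_alpha > 0), "dirichlet_alpha must be positive")
  assert_that(cfg$noise_sd >= 0, "noise_sd must be nonnegative")
  assert_that(cfg$beta_clip_eps > 0 && cfg$beta_clip_eps < 0.5,
              "beta_clip_eps must lie in (0, 0.5)")
  check_maf_range(cfg$maf_range)
  et <- cfg$effect_table
  if (nrow(et) > 0) {
    assert_that(all(et$cpg_index >= 1 & et$cpg_index <= cfg$n_cpgs),
                "effect_table cpg_index out of bounds")
    assert_that(all(et$variant_index >= 1 & et$variant_index <= cfg$n_variants),
                "effect_table variant_index out of bounds")
    assert_that(all(et$cell_type %in% cfg$cell_types),
                "effect_table cell_type not among configured cell types")
  }
  invisible(cfg)
}

check_maf_range <- function(maf_range) {
  assert_that(length(maf_range) == 2 && all(is.finite(maf_range)),
              "maf_range must be two finite frequencies")
  assert_that(all(maf_range > 0) && all(maf_range <= 0.5) &&
                maf_range[1] <= maf_range[2],
              "maf_range must lie within (0, 0.5]")
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Dosages are binomial(2, maf) per variant, i.e. variants in Hardy-Weinberg
#' equilibrium, emulating variants that have already passed standard QC.
#'
#' @param n_samples Number of individuals (>= 2).
#' @param n_variants Number of variants.
#' @param maf_range Range of minor allele frequencies within (0, 0.5];
#'   per-variant frequencies are drawn uniformly from it.
#' @param chrom Chromosome label.
#' @param positions Optional strictly increasing integer positions (1-based);
#'   by default variants are laid out every `spacing` bp.
#' @param spacing Default inter-variant spacing in bp.
#' @param seed Integer seed.
#' @return A list of class `imqtl_geno` with `dosage` (sample x variant
#'   matrix with values in 0/1/2) and `variants` (tibble of variant_id,
#'   chrom, pos, ref, alt, maf).
#' @export
simulate_genotypes <- function(n_samples, n_variants, maf_range = c(0.1, 0.5),
                               chrom = "1", positions = NULL, spacing = 1000L,
                               seed = 1L) {
  assert_that(n_samples >= 2, "n_samples must be at least 2")
  check_maf_range(maf_range)
  if (is.null(positions)) positions <- seq_len(n_variants) * spacing
  assert_that(length(positions) == n_variants && all(diff(positions) > 0),
              "positions must be strictly increasing, one per variant")
  set.seed(seed)
  maf <- runif(n_variants, maf_range[1], maf_range[2])
  dosage <- matrix(rbinom(n_samples * n_variants, 2, rep(maf, each = n_samples)),
                   nrow = n_samples)
  ids <- variant_ids(chrom, positions)
  dimnames(dosage) <- list(sample_ids(n_samples), ids)
  structure(list(
    dosage = dosage,
    variants = tibble(variant_id = ids, chrom = chrom,
                      pos = as.integer(positions), ref = "A", alt = "G",
                      maf = maf)
  ), class = "imqtl_geno")
}

#' Simulate Dirichlet cell-type proportions
#'
#' @param n_samples Number of individuals.
#' @param dirichlet_alpha Named positive concentration vector (K >= 2). The
#'   concentration sum controls the between-individual variance of the
#'   composition: component k has variance
#'   `mean_k (1 - mean_k) / (sum(alpha) + 1)`.
#' @param seed Integer seed.
#' @return Tibble with `sample_id` and one column per cell type; rows sum
#'   to 1.
#' @export
simulate_proportions <- function(n_samples, dirichlet_alpha, seed = 1L) {
  assert_that(length(dirichlet_alpha) >= 2, "at least two cell types required")
  assert_that(all(dirichlet_alpha > 0), "dirichlet_alpha must be positive")
  nms <- names(dirichlet_alpha) %||% paste0("cell", seq_along(dirichlet_alpha))
  if (is.null(names(dirichlet_alpha))) names(dirichlet_alpha) <- nms
  set.seed(seed)
  p <- rdirichlet_mat(n_samples, dirichlet_alpha)
  colnames(p) <- nms
  dplyr::bind_cols(tibble(sample_id = sample_ids(n_samples)), as_tibble(p))
}

proportions_matrix <- function(proportions) {
  m <- as.matrix(proportions[setdiff(names(proportions), "sample_id")])
  rownames(m) <- proportions$sample_id
  m
}

#' Simulate bulk methylation as a cell-type mixture
#'
#' The observed bulk beta value of sample i at CpG j is
#' `sum_k pi_ik (m_jk + b_jk g_i) + e_ij`, where `m_jk` is the cell-type
#' baseline methylome, `b_jk` is nonzero only for planted effects (acting on
#' the dosage of the planted variant within the planted cell type), and the
#' residual is Gaussian on the beta scale, clipped to
#' `[eps, 1 - eps]`. This makes explicit the generative model that
#' genotype-by-cell-type interaction regressions assume: a positive planted
#' beta-scale effect in cell k induces a positive fitted interaction
#' coefficient for cell k.
#'
#' @param genotypes `imqtl_geno` object (see [simulate_genotypes()]).
#' @param proportions Proportion tibble (see [simulate_proportions()]).
#' @param config `imqtl_config` object.
#' @param baselines Optional CpG x cell-type baseline matrix on the beta
#'   scale; drawn from the config's baseline model when omitted.
#' @return A list of class `imqtl_sim`: `genotypes`, `proportions`,
#'   `bulk_beta` (CpG x sample), `cpgs` (tibble cpg_id/chrom/pos),
#'   `baselines`, `covariates` (sample_id, age, sex) and `truth` (the planted
#'   effect table with resolved ids).
#' @export
simulate_bulk_methylation <- function(genotypes, proportions, config,
                                      baselines = NULL) {
  validate_config(config)
  pim <- proportions_matrix(proportions)
  n <- nrow(pim)
  assert_that(n == nrow(genotypes$dosage),
              "genotypes and proportions disagree on sample count")
  assert_that(identical(colnames(pim), config$cell_types),
              "proportion columns must match config cell_types")
  j <- config$n_cpgs
  k <- length(config$cell_types)
  set.seed(child_seed(config$seed, 2L))
  if (is.null(baselines)) {
    grand <- runif(j, config$baseline_range[1], config$baseline_range[2])
    baselines <- matrix(pmin(pmax(
      grand + rnorm(j * k, 0, config$celltype_baseline_sd), 0.02), 0.98),
      nrow = j)
  }
  assert_that(nrow(baselines) == j && ncol(baselines) == k,
              "baselines must be n_cpgs x n_cell_types")
  colnames(baselines) <- config$cell_types

  # CpG positions interleaved with the variant map so cis windows are busy
  span <- range(genotypes$variants$pos)
  cpg_pos <- as.integer(round(seq(span[1], span[2], length.out = j)))
  cpg_pos <- cpg_pos + seq_len(j) %% 7L # break exact ties with variants
  cpgs <- tibble(cpg_id = cpg_ids(j), chrom = genotypes$variants$chrom[1],
                 pos = cpg_pos)

  # signal: per (cpg, cell) slope matrix applied to the planted variant dosage
  effect_mu <- matrix(0, nrow = j, ncol = n) # CpG x sample genetic shift
  et <- config$effect_table
  if (nrow(et) > 0) {
    for (r in seq_len(nrow(et))) {
      g <- genotypes$dosage[, et$variant_index[r]]
      pik <- pim[, et$cell_type[r]]
      effect_mu[et$cpg_index[r], ] <- effect_mu[et$cpg_index[r], ] +
        et$effect[r] * g * pik
      worst <- max(abs(et$effect[r]) * 2) # dosage 2, proportion 1
      centre <- baselines[et$cpg_index[r], et$cell_type[r]]
      if (centre + worst > 1.5 || centre - worst < -0.5) {
        warn(sprintf("planted effect at cpg_index %d pushes mean beta far outside (0,1)",
                     et$cpg_index[r]))
      }
    }
  }

  mixture <- baselines %*% t(pim) # CpG x sample
  eps <- config$beta_clip_eps
  noise <- if (config$noise_sd > 0) {
    matrix(rnorm(j * n, 0, config$noise_sd), nrow = j)
  } else 0

  age <- rnorm(n, 50, 10)
  sex <- rbinom(n, 1, 0.5)
  covar_shift <- outer(rep(config$age_effect, j), age - 50) +
    outer(rep(config$sex_effect, j), sex)

  bulk <- pmin(pmax(mixture + effect_mu + covar_shift + noise, eps), 1 - eps)
  dimnames(bulk) <- list(cpgs$cpg_id, rownames(pim))

  truth <- if (nrow(et) > 0) {
    mutate(et,
           cpg_id = cpgs$cpg_id[.data$cpg_index],
           variant_id = genotypes$variants$variant_id[.data$variant_index])
  } else {
    mutate(et, cpg_id = character(), variant_id = character())
  }

  structure(list(
    genotypes = genotypes,
    proportions = proportions,
    bulk_beta = bulk,
    cpgs = cpgs,
    baselines = baselines,
    covariates = tibble(sample_id = rownames(pim), age = age, sex = sex),
    truth = truth
  ), class = "imqtl_sim")
}

#' Simulate a full study in one call
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_proportions()] and [simulate_bulk_methylation()] off a single
#' configuration; each stage consumes a distinct child seed.
#'
#' @param config `imqtl_config` object.
#' @return An `imqtl_sim` object.
#' @export
simulate_study <- function(config) {
  validate_config(config)
  geno <- simulate_genotypes(config$n_samples, config$n_variants,
                             config$maf_range, seed = child_seed(config$seed, 0L))
  alpha <- setNames(config$dirichlet_alpha, config$cell_types)
  props <- simulate_proportions(config$n_samples, alpha,
                                seed = child_seed(config$seed, 1L))
  simulate_bulk_methylation(geno, props, config)
}

#' Simulate sorted-cell reference methylomes
#'
#' Generates per-cell-type sorted samples in which planted differentially
#' methylated cytosines (DMCs) are hypomethylated in their target cell type
#' by a stated beta difference relative to all other types, while non-DMC
#' CpGs share a common mean across types. This emulates the sorted-cell
#' input from which a deconvolution reference panel is constructed.
#'
#' @param cell_types Character vector of cell-type names.
#' @param n_per_type Samples per cell type.
#' @param n_cpgs Total number of CpGs.
#' @param planted_dmcs Tibble with columns `cpg_index`, `cell_type`, `delta`
#'   (hypomethylation depth on the beta scale, in (0, 1]).
#' @param noise_sd Beta-scale noise SD of sorted profiles.
#' @param dmc_base Methylation level of DMC CpGs in non-target cell types.
#' @param seed Integer seed.
#' @return List of class `imqtl_sorted` with `beta` (CpG x sample matrix),
#'   `labels` (cell type per sample) and `truth` (the planted DMC table with
#'   cpg ids).
#' @export
simulate_sorted_reference <- function(cell_types, n_per_type, n_cpgs,
                                      planted_dmcs = NULL, noise_sd = 0.02,
                                      dmc_base = 0.96, seed = 1L) {
  if (is.null(planted_dmcs)) {
    planted_dmcs <- tibble(cpg_index = integer(), cell_type = character(),
                           delta = numeric())
  }
  planted_dmcs <- as_tibble(planted_dmcs)
  if (nrow(planted_dmcs) > 0) {
    assert_that(all(planted_dmcs$delta > 0 & planted_dmcs$delta <= 1),
                "planted DMC delta must lie in (0, 1]")
    assert_that(all(planted_dmcs$cell_type %in% cell_types),
                "planted DMC cell_type not among cell_types")
    assert_that(all(planted_dmcs$cpg_index >= 1 &
                      planted_dmcs$cpg_index <= n_cpgs),
                "planted DMC cpg_index out of bounds")
    assert_that(!anyDuplicated(planted_dmcs$cpg_index),
                "each CpG may be planted as a DMC for at most one cell type")
  }
  set.seed(seed)
  n_total <- n_per_type * length(cell_types)
  labels <- rep(cell_types, each = n_per_type)
  base <- runif(n_cpgs, 0.2, 0.8)
  base[planted_dmcs$cpg_index] <- dmc_base
  beta <- matrix(rep(base, n_total), nrow = n_cpgs)
  if (nrow(planted_dmcs) > 0) {
    for (r in seq_len(nrow(planted_dmcs))) {
      tgt <- labels == planted_dmcs$cell_type[r]
      beta[planted_dmcs$cpg_index[r], tgt] <-
        dmc_base - planted_dmcs$delta[r]
    }
  }
  beta <- pmin(pmax(beta + matrix(rnorm(length(beta), 0, noise_sd),
                                  nrow = n_cpgs), 1e-3), 1 - 1e-3)
  ids <- cpg_ids(n_cpgs)
  dimnames(beta) <- list(ids, sprintf("%s_%02d", labels,
                                      sequence(rep(n_per_type,
                                                   length(cell_types)))))
  truth <- mutate(planted_dmcs, cpg_id = ids[.data$cpg_index])
  structure(list(beta = beta, labels = labels, truth = truth),
            class = "imqtl_sorted")
}

#' Simulate a pair of summary-statistic tracks
#'
#' Two traits are regressed variant-by-variant on the same genotype panel,
#' yielding the per-variant effect/SE tracks a colocalization analysis
#' consumes. The causal configuration is recorded as ground truth:
#' `"none"` (neither trait has a causal variant), `"shared"` (both traits
#' driven by the same variant) or `"distinct"` (two different causal
#' variants).
#'
#' @param n_variants Number of variants at the locus.
#' @param causal_config One of "none", "shared", "distinct".
#' @param n1,n2 Sample sizes of the two traits.
#' @param effect_z Target expected association z-score at the causal variant.
#' @param maf Minor allele frequency of the panel.
#' @param ld_r Correlation between neighbouring variants (simple uniform LD:
#'   each non-causal genotype copies the causal one with probability
#'   `ld_r^2`, emulating block-correlated variants).
#' @param duplicate_traits If TRUE (requires `n1 == n2` and a shared causal
#'   configuration or none), trait 2 reuses trait 1's phenotype vector, so
#'   both tracks carry identical per-variant statistics.
#' @param seed Integer seed.
#' @return List with `stats1`, `stats2` (tibbles: variant_id, pos, ref, alt,
#'   beta, se, p, maf, n) and `truth` (causal_config plus causal indices).
#' @export
simulate_summary_pair <- function(n_variants, causal_config = c("none", "shared", "distinct"),
                                  n1 = 500, n2 = 500, effect_z = 8,
                                  maf = 0.3, ld_r = 0,
                                  duplicate_traits = FALSE, seed = 1L) {
  causal_config <- match.arg(causal_config)
  assert_that(n_variants >= 1, "n_variants must be positive")
  if (causal_config == "distinct") {
    assert_that(n_variants >= 2,
                "distinct causal variants require at least 2 variants")
  }
  set.seed(seed)
  n <- max(n1, n2)
  g0 <- rbinom(n, 2, maf)
  geno <- sapply(seq_len(n_variants), function(i) {
    keep <- runif(n) < ld_r^2
    ifelse(keep, g0, rbinom(n, 2, maf))
  })
  causal <- switch(causal_config,
                   none = c(NA_integer_, NA_integer_),
                   shared = rep(sample.int(n_variants, 1), 2),
                   distinct = sample.int(n_variants, 2))
  sd_g <- sqrt(2 * maf * (1 - maf))
  make_trait <- function(nn, cv, y = NULL) {
    b <- if (is.na(cv)) 0 else effect_z / (sd_g * sqrt(nn))
    idx <- seq_len(nn)
    if (is.null(y)) {
      y <- rnorm(nn) + if (is.na(cv)) 0 else b * geno[idx, cv]
    }
    # per-variant simple OLS, vectorized
    gg <- geno[idx, , drop = FALSE]
    gc <- sweep(gg, 2, colMeans(gg))
    yc <- y - mean(y)
    sxx <- colSums(gc^2)
    est <- colSums(gc * yc) / sxx
    rss <- sum(yc^2) - est^2 * sxx
    se2 <- rss / (nn - 2) / sxx
    stats <- rbind(est, sqrt(se2),
                   2 * pt(abs(est / sqrt(se2)), nn - 2, lower.tail = FALSE))
    stats[, sxx == 0] <- NA
    list(y = y,
         stats = tibble(variant_id = sprintf("chr1_%d", seq_len(n_variants) * 1000L),
                        pos = seq_len(n_variants) * 1000L, ref = "A", alt = "G",
                        beta = stats[1, ], se = stats[2, ], p = stats[3, ],
                        maf = colMeans(geno[idx, , drop = FALSE]) / 2, n = nn))
  }
  t1 <- make_trait(n1, causal[1])
  t2 <- if (duplicate_traits) {
    assert_that(n1 == n2, "duplicate_traits requires n1 == n2")
    make_trait(n2, causal[2], y = t1$y)
  } else {
    make_trait(n2, causal[2])
  }
  structure(list(stats1 = t1$stats, stats2 = t2$stats,
                 truth = list(causal_config = causal_config,
                              causal_index = causal)),
            class = "imqtl_sumpair")
}
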
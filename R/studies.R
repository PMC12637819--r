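# Simulation-study drivers: parameter recovery, family-wise error
# calibration, power versus composition variance, panel validation, and
# colocalization calibration. These run the full pipeline on generated data
# with known truth; the methods vignette documents the study conditions.

#' Recovery of a planted cell-type-specific interaction effect
#'
#' Each replicate simulates a two-component tissue — a minor, highly
#' variable target cell type against the remaining tissue, proportions
#' Dirichlet(0.15, 0.85) — with one planted beta-scale effect `b` acting in
#' the target type only, fits the interaction model for both cell types,
#' runs the stratified associations, and applies the cell-type-specificity
#' criteria to each type.
#'
#' @param n_reps Number of replicates.
#' @param n_samples Samples per replicate.
#' @param b Planted beta-scale effect per dosage unit.
#' @param noise_sd Beta-scale residual SD.
#' @param alpha Dirichlet concentrations of (target, rest).
#' @param maf Variant minor allele frequency.
#' @param seed Integer seed.
#' @return List with `replicates` (per-replicate tibble) and `summary`
#'   (percent sign recovery, percent correct specificity pattern).
#' @export
run_recovery_study <- function(n_reps = 200, n_samples = 2000, b = 0.2,
                               noise_sd = 0.05, alpha = c(0.15, 0.85),
                               maf = 0.3, seed = 1L) {
  cells <- c("target", "rest")
  baselines <- matrix(c(0.3, 0.6), nrow = 1,
                      dimnames = list(NULL, cells))
  reps <- map_dfr(seq_len(n_reps), function(r) {
    cfg <- simulation_config(
      n_samples = n_samples, n_variants = 1, n_cpgs = 1,
      maf_range = c(maf, maf), cell_types = cells, dirichlet_alpha = alpha,
      effect_table = tibble(cpg_index = 1L, variant_index = 1L,
                            cell_type = "target", effect = b),
      noise_sd = noise_sd, seed = child_seed(seed, r))
    sim <- simulate_study_with_baselines(cfg, baselines)
    y <- rank_inverse_normal(beta_to_mvalue(sim$bulk_beta[1, ]))
    g <- sim$genotypes$dosage[, 1]
    covm <- cbind(age = sim$covariates$age, sex = sim$covariates$sex)
    ifits <- map_dfr(cells, function(ct) {
      c_int <- rank_inverse_normal(sim$proportions[[ct]])
      mutate(fit_interaction_model(y, g, c_int, covm), cell_type = ct)
    })
    sfits <- map_dfr(cells, function(ct) {
      mutate(stratified_association(y, g, sim$proportions[[ct]], "upper",
                                    covm), cell_type = ct)
    })
    calls <- map_lgl(cells, function(ct) {
      call_cell_type_specific(ct, ifits, sfits)$specific
    })
    tibble(rep = r,
           beta_gxc_target = ifits$beta_gxc[ifits$cell_type == "target"],
           sign_ok = ifits$beta_gxc[ifits$cell_type == "target"] * b > 0,
           target_called = calls[1], rest_called = calls[2])
  })
  list(replicates = reps,
       summary = tibble(
         pct_sign_recovered = 100 * mean(reps$sign_ok),
         pct_correct_specificity = 100 * mean(reps$target_called &
                                                !reps$rest_called)))
}

# simulate_study with explicit per-CpG baselines (shared across replicates)
simulate_study_with_baselines <- function(config, baselines) {
  geno <- simulate_genotypes(config$n_samples, config$n_variants,
                             config$maf_range,
                             seed = child_seed(config$seed, 0L))
  alpha <- setNames(config$dirichlet_alpha, config$cell_types)
  props <- simulate_proportions(config$n_samples, alpha,
                                seed = child_seed(config$seed, 1L))
  simulate_bulk_methylation(geno, props, config, baselines = baselines)
}

#' Family-wise error calibration of the EMT + Bonferroni scheme
#'
#' Simulates null studies (no planted effects), runs the full interaction
#' scan with the effective-number-of-tests and Bonferroni corrections, and
#' reports the fraction of studies declaring any significant imQTL.
#'
#' @param n_studies Number of simulated null studies.
#' @param n_samples,n_cpgs,n_variants Per-study dimensions.
#' @param cell_type Modeled cell type (first configured type by default).
#' @param seed Integer seed.
#' @return List with `rejections` (logical per study), `fwer` and the
#'   Monte-Carlo standard error of the nominal level.
#' @export
run_fwer_study <- function(n_studies = 200, n_samples = 200, n_cpgs = 50,
                           n_variants = 20, cell_type = "epithelial",
                           seed = 1L) {
  rej <- vapply(seq_len(n_studies), function(s) {
    cfg <- simulation_config(n_samples = n_samples, n_variants = n_variants,
                             n_cpgs = n_cpgs, seed = child_seed(seed, s))
    sim <- simulate_study(cfg)
    scan <- map_interaction_mqtls(sim$genotypes, sim$bulk_beta, sim$cpgs,
                                  sim$proportions, cell_type,
                                  covariates = sim$covariates)
    any(scan$leads$significant)
  }, logical(1))
  list(rejections = rej, fwer = mean(rej),
       mc_se = sqrt(0.05 * 0.95 / n_studies))
}

#' Detection power versus composition variance
#'
#' At a fixed mean proportion and planted effect size, varies the Dirichlet
#' concentration of a two-component composition across settings of
#' increasing between-individual variance and records the fraction of
#' replicates with a nominally significant interaction term.
#'
#' @param concentrations Dirichlet concentration sums, high to low (variance
#'   increases as concentration falls).
#' @param mean_prop Mean proportion of the modeled cell type.
#' @param n_reps Replicates per setting.
#' @param n_samples Samples per replicate.
#' @param b Planted beta-scale effect.
#' @param noise_sd Beta-scale residual SD.
#' @param maf Variant minor allele frequency.
#' @param seed Integer seed.
#' @return Tibble with `concentration`, `prop_variance`, `power`.
#' @export
run_power_curve <- function(concentrations = c(40, 8, 2), mean_prop = 0.25,
                            n_reps = 200, n_samples = 200, b = 0.15,
                            noise_sd = 0.05, maf = 0.3, seed = 1L) {
  cells <- c("target", "rest")
  baselines <- matrix(c(0.3, 0.6), nrow = 1, dimnames = list(NULL, cells))
  map_dfr(seq_along(concentrations), function(ci) {
    conc <- concentrations[ci]
    hits <- vapply(seq_len(n_reps), function(r) {
      cfg <- simulation_config(
        n_samples = n_samples, n_variants = 1, n_cpgs = 1,
        maf_range = c(maf, maf), cell_types = cells,
        dirichlet_alpha = c(mean_prop, 1 - mean_prop) * conc,
        effect_table = tibble(cpg_index = 1L, variant_index = 1L,
                              cell_type = "target", effect = b),
        noise_sd = noise_sd, seed = child_seed(seed, ci * 100000L + r))
      sim <- simulate_study_with_baselines(cfg, baselines)
      y <- rank_inverse_normal(beta_to_mvalue(sim$bulk_beta[1, ]))
      fit <- fit_interaction_model(
        y, sim$genotypes$dosage[, 1],
        rank_inverse_normal(sim$proportions$target))
      fit$p_gxc < 0.05
    }, logical(1))
    tibble(concentration = conc,
           prop_variance = mean_prop * (1 - mean_prop) / (conc + 1),
           power = mean(hits))
  })
}

#' Build and validate a reference panel on synthetic sorted data
#'
#' Simulates sorted-cell training data with planted cell-type-specific
#' hypomethylation (default counts 62/65/60/66 DMCs for immune, epithelial,
#' fibroblast and endothelial cells), builds the panel, then validates it on
#' independently simulated held-out sorted samples via noisy in-silico
#' mixtures.
#'
#' @param dmc_counts Named planted DMC counts per cell type.
#' @param deltas Named planted hypomethylation depths (each above its type's
#'   selection threshold).
#' @param n_background Non-discriminating CpGs added to the array.
#' @param n_per_type Sorted training samples per cell type.
#' @param n_holdout Held-out sorted samples per cell type.
#' @param n_mixtures In-silico mixtures for validation.
#' @param noise_sd Beta-scale noise added to each mixture.
#' @param seed Integer seed.
#' @return List with `panel`, `validation` (per-cell-type r and RMSE) and
#'   `truth` (planted DMC table).
#' @export
run_panel_study <- function(dmc_counts = c(immune = 62, epithelial = 65,
                                           fibroblast = 60, endothelial = 66),
                            deltas = c(immune = 0.93, epithelial = 0.83,
                                       fibroblast = 0.84, endothelial = 0.75),
                            n_background = 800, n_per_type = 12,
                            n_holdout = 6, n_mixtures = 500, noise_sd = 0.05,
                            seed = 1L) {
  cells <- names(dmc_counts)
  n_dmcs <- sum(dmc_counts)
  planted <- tibble(
    cpg_index = seq_len(n_dmcs),
    cell_type = rep(cells, times = dmc_counts),
    delta = rep(deltas[cells], times = dmc_counts))
  n_cpgs <- n_dmcs + n_background
  train <- simulate_sorted_reference(cells, n_per_type, n_cpgs, planted,
                                     seed = child_seed(seed, 0L))
  panel <- build_reference_panel(train$beta, train$labels)
  holdout <- simulate_sorted_reference(cells, n_holdout, n_cpgs, planted,
                                       seed = child_seed(seed, 1L))
  validation <- validate_panel_insilico(panel, holdout$beta, holdout$labels,
                                        n_mixtures = n_mixtures,
                                        noise_sd = noise_sd,
                                        seed = child_seed(seed, 2L))
  list(panel = panel, validation = validation, truth = train$truth)
}

#' Colocalization calibration on simulated locus pairs
#'
#' Repeatedly simulates a pair of summary-statistic tracks under a known
#' causal configuration and records the posterior mass on the matching
#' hypothesis.
#'
#' @param n_reps Replicates.
#' @param causal_config "shared", "none" or "distinct".
#' @param n_variants Variants per locus.
#' @param effect_z Expected causal z-score.
#' @param n1,n2 Trait sample sizes.
#' @param priors [coloc_priors()] used for enumeration.
#' @param seed Integer seed.
#' @return Tibble with one row per replicate: `pp0`..`pp4` and the truth.
#' @export
run_coloc_calibration <- function(n_reps = 100, causal_config = "shared",
                                  n_variants = 50, effect_z = 8, n1 = 500,
                                  n2 = 500, priors = coloc_priors(),
                                  seed = 1L) {
  map_dfr(seq_len(n_reps), function(r) {
    pair <- simulate_summary_pair(n_variants, causal_config, n1 = n1,
                                  n2 = n2, effect_z = effect_z,
                                  seed = child_seed(seed, r))
    res <- coloc_enumerate(pair$stats1, pair$stats2, priors)
    mutate(res, rep = r, causal_config = causal_config)
  })
}
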
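test_that("stratified MAF filter matches a brute-force recount", {
  set.seed(41)
  geno <- simulate_genotypes(200, 40, maf_range = c(0.05, 0.4), seed = 41)
  prop <- runif(200)
  keep <- stratified_maf_filter(geno$dosage, prop)
  upper <- prop > median(prop)
  brute <- vapply(seq_len(40), function(v) {
    f_up <- mean(geno$dosage[upper, v]) / 2
    f_lo <- mean(geno$dosage[!upper, v]) / 2
    min(f_up, 1 - f_up) > 0.1 && min(f_lo, 1 - f_lo) > 0.1
  }, logical(1))
  expect_identical(unname(keep), brute)
  # allele present only in one half is removed
  g2 <- geno
  g2$dosage[, 1] <- ifelse(upper, 0, rbinom(200, 2, 0.4))
  expect_false(stratified_maf_filter(g2$dosage, prop)[1])
  expect_error(stratified_maf_filter(geno$dosage[1:3, ], prop[1:3]), "4 samples")
})

test_that("scan engine equals the per-pair least-squares reference", {
  sim <- make_study(n_samples = 120, n_variants = 15, n_cpgs = 8, seed = 42)
  scan <- map_interaction_mqtls(sim$genotypes, sim$bulk_beta, sim$cpgs,
                                sim$proportions, "epithelial",
                                covariates = sim$covariates)
  Y <- int_mvalues(sim$bulk_beta)
  c_int <- rank_inverse_normal(sim$proportions$epithelial)
  covm <- cbind(age = sim$covariates$age, sex = sim$covariates$sex)
  idx <- sample(nrow(scan$associations), 40)
  for (i in idx) {
    a <- scan$associations[i, ]
    ref <- fit_interaction_model(Y[a$cpg_id, ],
                                 sim$genotypes$dosage[, a$variant_id],
                                 c_int, covm)
    for (cl in c("beta_main", "se_main", "p_main", "beta_cell", "beta_gxc",
                 "se_gxc", "p_gxc")) {
      expect_equal(a[[cl]], ref[[cl]], tolerance = 1e-8)
    }
  }
})

test_that("effective number of tests reflects the correlation structure", {
  set.seed(43)
  g <- rbinom(500, 2, 0.3)
  # identical columns count once
  expect_identical(emt_estimate(cbind(g, g, g)), 1L)
  # independent variants count nearly fully
  gi <- matrix(rbinom(500 * 20, 2, 0.3), 500, 20)
  m_eff <- emt_estimate(gi)
  expect_gte(m_eff, 18)
  expect_lte(m_eff, 20)
  # constant column excluded with a warning
  expect_warning(m1 <- emt_estimate(cbind(g, rep(1, 500))), "constant")
  expect_identical(m1, 1L)
})

test_that("multiple-testing arithmetic is monotone and respects identities", {
  sim <- make_study(n_samples = 100, n_variants = 12, n_cpgs = 6, seed = 44)
  scan <- map_interaction_mqtls(sim$genotypes, sim$bulk_beta, sim$cpgs,
                                sim$proportions, "epithelial",
                                covariates = sim$covariates)
  l <- scan$leads
  expect_true(all(l$p_emt >= l$p_min - 1e-15))
  expect_true(all(l$p_bonf >= l$p_emt - 1e-15))
  expect_true(all(l$p_emt <= 1 & l$p_bonf <= 1))
  # single CpG, single variant: p_bonf equals the raw p
  g1 <- simulate_genotypes(100, 1, maf_range = c(0.3, 0.3), seed = 45)
  cfg <- simulation_config(n_samples = 100, n_variants = 1, n_cpgs = 1,
                           seed = 45)
  props <- simulate_proportions(100, setNames(cfg$dirichlet_alpha,
                                              cfg$cell_types), seed = 46)
  sim1 <- simulate_bulk_methylation(g1, props, cfg)
  scan1 <- map_interaction_mqtls(sim1$genotypes, sim1$bulk_beta, sim1$cpgs,
                                 sim1$proportions, "epithelial")
  expect_equal(scan1$leads$p_bonf, scan1$leads$p_gxc, tolerance = 1e-12)
  expect_identical(scan1$leads$m_eff, 1L)
})

test_that("perfectly correlated variants collapse to one effective test", {
  set.seed(47)
  n <- 120
  g <- rbinom(n, 2, 0.4)
  dosage <- cbind(v1 = g, v2 = g, v3 = g)
  geno <- structure(list(
    dosage = matrix(dosage, n, dimnames = list(sprintf("S%04d", 1:n),
                                               c("v1", "v2", "v3"))),
    variants = tibble::tibble(variant_id = c("v1", "v2", "v3"), chrom = "1",
                              pos = c(1000L, 2000L, 3000L), ref = "A",
                              alt = "G", maf = 0.4)), class = "imqtl_geno")
  meth <- matrix(runif(n, 0.3, 0.7), 1, n,
                 dimnames = list("cg0000001", sprintf("S%04d", 1:n)))
  cpgs <- tibble::tibble(cpg_id = "cg0000001", chrom = "1", pos = 1500L)
  props <- tibble::tibble(sample_id = sprintf("S%04d", 1:n),
                          epithelial = runif(n), rest = 1 - runif(n))
  scan <- map_interaction_mqtls(geno, meth, cpgs, props, "epithelial")
  expect_identical(scan$leads$m_eff, 1L)
  expect_equal(scan$leads$p_emt, scan$leads$p_min, tolerance = 1e-12)
})

test_that("null interaction p-values are uniform", {
  cfg <- simulation_config(n_samples = 150, n_variants = 50, n_cpgs = 100,
                           maf_range = c(0.2, 0.5), seed = 48)
  sim <- simulate_study(cfg)
  scan <- map_interaction_mqtls(sim$genotypes, sim$bulk_beta, sim$cpgs,
                                sim$proportions, "epithelial",
                                covariates = sim$covariates)
  expect_gte(nrow(scan$associations), 5000)
  ks <- suppressWarnings(stats::ks.test(scan$associations$p_gxc, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted interaction effects yield significant correctly-signed leads", {
  et <- tibble::tibble(cpg_index = 3L, variant_index = 10L,
                       cell_type = "epithelial", effect = 0.25)
  sim <- make_study(n_samples = 600, n_variants = 20, n_cpgs = 6,
                    effect_table = et, seed = 49)
  scan <- map_interaction_mqtls(sim$genotypes, sim$bulk_beta, sim$cpgs,
                                sim$proportions, "epithelial",
                                covariates = sim$covariates)
  lead <- scan$leads[scan$leads$cpg_id == sim$truth$cpg_id, ]
  expect_true(lead$significant)
  expect_identical(lead$variant_id, sim$truth$variant_id)
  expect_gt(lead$beta_gxc, 0)
  # marginal scan sees the diluted effect with the same sign
  marg <- map_marginal_mqtls(sim$genotypes, sim$bulk_beta, sim$cpgs,
                             covariates = sim$covariates)
  mrow <- marg$associations[marg$associations$cpg_id == sim$truth$cpg_id &
                              marg$associations$variant_id ==
                                sim$truth$variant_id, ]
  expect_gt(mrow$beta_main, 0)
  expect_lt(mrow$p_main, 1e-3)
})

test_that("conditional scan finds a second signal and skips collinear candidates", {
  et <- tibble::tibble(cpg_index = c(2L, 2L), variant_index = c(5L, 15L),
                       cell_type = "epithelial", effect = c(0.3, 0.3))
  sim <- make_study(n_samples = 800, n_variants = 20, n_cpgs = 4,
                    effect_table = et, seed = 50)
  lead_id <- sim$genotypes$variants$variant_id[5]
  second_id <- sim$genotypes$variants$variant_id[15]
  sec <- conditional_secondary_scan(sim$genotypes, sim$bulk_beta, sim$cpgs,
                                    sim$proportions, "epithelial",
                                    cpg_id = sim$cpgs$cpg_id[2],
                                    lead_variant = lead_id,
                                    covariates = sim$covariates)
  expect_true(second_id %in% sec$variant_id)
  # duplicate of the lead is skipped
  geno2 <- sim$genotypes
  geno2$dosage <- cbind(geno2$dosage, dup = geno2$dosage[, 5])
  colnames(geno2$dosage)[21] <- "dup"
  geno2$variants <- dplyr::bind_rows(
    geno2$variants,
    dplyr::mutate(geno2$variants[5, ], variant_id = "dup", pos = pos + 1L))
  sec2 <- conditional_secondary_scan(geno2, sim$bulk_beta, sim$cpgs,
                                     sim$proportions, "epithelial",
                                     cpg_id = sim$cpgs$cpg_id[2],
                                     lead_variant = lead_id,
                                     covariates = sim$covariates)
  expect_true("dup" %in% attr(sec2, "skipped"))
})

test_that("single planted signal rarely produces secondary candidates", {
  hits <- vapply(1:10, function(r) {
    et <- tibble::tibble(cpg_index = 1L, variant_index = 3L,
                         cell_type = "epithelial", effect = 0.3)
    sim <- suppressWarnings(
      make_study(n_samples = 400, n_variants = 10, n_cpgs = 2,
                 effect_table = et, seed = 500 + r))
    sec <- conditional_secondary_scan(sim$genotypes, sim$bulk_beta, sim$cpgs,
                                      sim$proportions, "epithelial",
                                      cpg_id = sim$cpgs$cpg_id[1],
                                      lead_variant = sim$truth$variant_id[1],
                                      covariates = sim$covariates)
    nrow(sec) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("pleiotropy counts match a brute-force recount", {
  assoc <- tibble::tibble(
    variant_id = rep(c("v1", "v2"), each = 6),
    cpg_id = rep(sprintf("cg%d", 1:3), 4),
    p_gxc = c(1e-6, 1e-5, 0.5, 1e-7, 0.2, 0.9,
              0.5, 0.6, 0.7, 0.8, 0.9, 0.99))
  expect_identical(pleiotropy_count("v1", assoc), 2L)
  expect_identical(pleiotropy_count("v2", assoc), 0L)
  brute <- length(unique(assoc$cpg_id[assoc$variant_id == "v1" &
                                        assoc$p_gxc < 1e-4]))
  expect_identical(pleiotropy_count("v1", assoc), brute)
})
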
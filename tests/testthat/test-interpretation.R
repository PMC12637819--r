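test_that("directional-consistency classes partition every imQTL", {
  imqtls <- tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v4"),
    cpg_id = c("cg1", "cg2", "cg3", "cg4"),
    cell_type = "epithelial",
    beta_gxc = c(0.5, 0.5, -0.5, 0.4),
    p_gxc = 1e-8)
  marginals <- tibble::tibble(
    variant_id = c("v1", "v2", "v3"),
    cpg_id = c("cg1", "cg2", "cg3"),
    beta_main = c(0.3, 0.3, 0.3),
    p_main = c(1e-10, 0.5, 1e-10))
  expect_message(out <- classify_directional_consistency(imqtls, marginals),
                 "lack a marginal record")
  expect_identical(out$class, c("consistent", "unknown", "inconsistent",
                                "unknown"))
  # exactly one class each
  expect_true(all(table(out$cpg_id) == 1))
  sm <- consistency_summary(out)
  expect_equal(sm$pct_consistent, 25)
})

test_that("stratified association halves partition samples and recover plants", {
  set.seed(61)
  n <- 400
  prop <- rbeta(n, 2, 2)
  upper <- prop > median(prop)
  expect_equal(sum(upper) + sum(prop <= median(prop)), n)
  g <- rbinom(n, 2, 0.3)
  y <- 0.3 * g * as.numeric(upper) + rnorm(n, 0, 0.5)
  up <- stratified_association(y, g, prop, "upper")
  lo <- stratified_association(y, g, prop, "lower")
  expect_equal(up$n + lo$n, n)
  expect_equal(up$slope, 0.3, tolerance = 0.15)
  expect_gt(lo$p, up$p)
  # monomorphic stratum is untestable
  g_mono <- ifelse(upper, 1, rbinom(n, 2, 0.5))
  expect_true(stratified_association(y, g_mono, prop, "upper")$untestable)
})

test_that("null stratified associations have uniform p-values", {
  set.seed(62)
  ps <- vapply(1:200, function(r) {
    n <- 60
    prop <- runif(n)
    stratified_association(rnorm(n), rbinom(n, 2, 0.3), prop, "upper")$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("cell-type-specificity criteria follow the sign/significance rules", {
  ifits <- tibble::tibble(cell_type = c("a", "b", "c"),
                          beta_gxc = c(0.5, -0.2, -0.1),
                          p_gxc = c(1e-9, 0.3, 0.6))
  sfits <- tibble::tibble(cell_type = c("a", "b", "c"),
                          slope = c(0.4, 0.1, 0.05),
                          p = c(0.001, 0.4, 0.7))
  expect_true(call_cell_type_specific("a", ifits, sfits)$specific)
  # same-sign nominally significant interaction in another type kills crit 1
  ifits2 <- ifits
  ifits2$beta_gxc[2] <- 0.3
  ifits2$p_gxc[2] <- 0.01
  expect_false(call_cell_type_specific("a", ifits2, sfits)$specific)
  # significant same-direction association in another type's stratum kills crit 2
  sfits2 <- sfits
  sfits2$p[2] <- 0.001
  expect_false(call_cell_type_specific("a", ifits, sfits2)$specific)
  # ... unless its direction is opposite
  sfits3 <- sfits2
  sfits3$slope[2] <- -0.3
  expect_true(call_cell_type_specific("a", ifits, sfits3)$specific)
  expect_error(call_cell_type_specific("a", ifits[1, ], sfits[1, ]),
               "at least 2")
})

test_that("effect sharing is 1 on the diagonal and for identical fit tables", {
  fits <- tidyr::expand_grid(pair_id = sprintf("p%d", 1:20),
                             cell_type = c("a", "b")) |>
    dplyr::mutate(beta_gxc = rep(rnorm(20), each = 2),
                  p_gxc = rep(runif(20, 0, 0.04), each = 2))
  sh <- effect_sharing_matrix(fits)
  expect_equal(unname(diag(sh$sharing)), c(1, 1))
  expect_equal(unname(sh$sharing["a", "b"]), 1)
  expect_equal(unname(sh$sharing["b", "a"]), 1)
})

test_that("planted lineages cluster together in the sharing matrix", {
  set.seed(63)
  n_pairs <- 60
  base1 <- rnorm(n_pairs) # lineage 1 effects (cells a, b)
  base2 <- rnorm(n_pairs) # lineage 2 effects (cells c, d)
  fits <- purrr::map_dfr(c("a", "b", "c", "d"), function(ct) {
    eff <- if (ct %in% c("a", "b")) base1 else base2
    tibble::tibble(pair_id = sprintf("p%d", 1:n_pairs), cell_type = ct,
                   beta_gxc = eff + rnorm(n_pairs, 0, 0.1),
                   p_gxc = runif(n_pairs, 0, 0.04))
  })
  sh <- effect_sharing_matrix(fits)
  within <- mean(c(sh$sharing["a", "b"], sh$sharing["b", "a"],
                   sh$sharing["c", "d"], sh$sharing["d", "c"]))
  between <- mean(c(sh$sharing["a", "c"], sh$sharing["a", "d"],
                    sh$sharing["b", "c"], sh$sharing["b", "d"]))
  expect_gt(within, between)
  # dendrogram order keeps lineages contiguous
  ord <- sh$order
  pos <- match(c("a", "b", "c", "d"), ord)
  expect_equal(abs(pos[1] - pos[2]), 1)
  expect_equal(abs(pos[3] - pos[4]), 1)
})

test_that("replication against the identical dataset validates everything", {
  disc <- tibble::tibble(variant_id = sprintf("v%d", 1:10),
                         cpg_id = sprintf("cg%d", 1:10),
                         cell_type = "epithelial",
                         beta_gxc = rnorm(10),
                         ref = "A", alt = "G")
  repl <- dplyr::mutate(disc, p_gxc = 1e-6)
  out <- replicate_imqtls(disc, repl)
  expect_equal(out$report$fraction_validated, 1)
  expect_equal(out$n_untestable, 0)
  # allele swap flips the sign and still validates
  repl_sw <- dplyr::mutate(repl, ref = "G", alt = "A", beta_gxc = -beta_gxc)
  out_sw <- replicate_imqtls(disc, repl_sw)
  expect_equal(out_sw$report$fraction_validated, 1)
  # non-matching alleles are a hard error
  repl_bad <- dplyr::mutate(repl, ref = "T")
  expect_error(replicate_imqtls(disc, repl_bad), "strand")
})

test_that("independent simulations of the same truth replicate strong imQTLs", {
  et <- tibble::tibble(cpg_index = 1:3, variant_index = c(4L, 10L, 16L),
                       cell_type = "epithelial", effect = 0.25)
  run_scan <- function(seed) {
    sim <- make_study(n_samples = 1000, n_variants = 20, n_cpgs = 6,
                      effect_table = et, seed = seed)
    list(sim = sim,
         scan = map_interaction_mqtls(sim$genotypes, sim$bulk_beta, sim$cpgs,
                                      sim$proportions, "epithelial",
                                      covariates = sim$covariates))
  }
  d <- run_scan(64)
  r <- run_scan(65)
  disc <- d$scan$leads[d$scan$leads$significant, ]
  expect_gte(nrow(disc), 2)
  repl_fits <- r$scan$associations
  out <- replicate_imqtls(
    dplyr::select(disc, variant_id, cpg_id, cell_type, beta_gxc),
    dplyr::select(repl_fits, variant_id, cpg_id, cell_type, beta_gxc, p_gxc))
  expect_gt(out$report$fraction_validated, 0.5)
})
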
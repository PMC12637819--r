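test_that("EWAS detects composition-driven CpGs and stays null otherwise", {
  cfg <- simulation_config(n_samples = 500, n_variants = 2, n_cpgs = 40,
                           celltype_baseline_sd = 0, seed = 71)
  sim <- simulate_study(cfg)
  # plant baseline differences of 0.3 for the first 5 CpGs in epithelial
  baselines <- sim$baselines
  baselines[1:5, "epithelial"] <- baselines[1:5, "epithelial"] - 0.3
  sim2 <- simulate_bulk_methylation(sim$genotypes, sim$proportions, cfg,
                                    baselines = baselines)
  y <- int_mvalues(sim2$bulk_beta)
  dms <- ewas_cell_proportion_dms(y, sim2$proportions$epithelial)
  expect_true(all(dms$is_dms[1:5]))
  null_p <- dms$p[6:40]
  expect_gt(suppressWarnings(stats::ks.test(null_p, "punif"))$p.value, 0.01)
  expect_error(ewas_cell_proportion_dms(y, rep(0.5, 500)), "constant")
})

test_that("DMS overlap fractions match brute-force set intersection", {
  dms <- sprintf("cg%03d", 1:40)
  target <- sprintf("cg%03d", 31:50)
  bg <- sprintf("cg%03d", 1:100)
  out <- proportion_in_dms(list(imqtl = target), dms, bg)
  expect_equal(out$fraction_in_dms[out$set == "imqtl"],
               length(intersect(target, dms)) / length(target))
  expect_equal(out$fraction_in_dms[out$set == "background"], 0.4)
  # subset fully inside, and empty DMS set
  expect_equal(proportion_in_dms(list(x = dms[1:5]), dms, bg)$fraction_in_dms[1], 1)
  expect_equal(proportion_in_dms(list(x = target), character(0), bg)$fraction_in_dms[1], 0)
})

test_that("Fisher enrichment matches closed forms and the hypergeometric oracle", {
  # balanced table: no enrichment
  ann <- tibble::tibble(chrom = "1", start = 0L, end = 1000L, label = "ann")
  target <- tibble::tibble(chrom = "1", pos = c(1:5 * 100L, 10001:10005))
  bg <- dplyr::bind_rows(target,
                         tibble::tibble(chrom = "1",
                                        pos = c(6:10 * 100L, 10006:10010)))
  out <- fisher_enrichment(target, bg, ann)
  expect_equal(out$log_or, 0)
  expect_equal(out$p, 1)
  # (10, 90; 10, 890): OR ~ 9.889, p matches the hypergeometric sum
  ann2 <- tibble::tibble(chrom = "1", start = 0L, end = 100L, label = "a2")
  t2 <- tibble::tibble(chrom = "1", pos = c(1:10, 1001:1090))
  b2 <- dplyr::bind_rows(t2, tibble::tibble(chrom = "1",
                                            pos = c(11:20, 2001:2890)))
  out2 <- fisher_enrichment(t2, b2, ann2)
  expect_equal(out2$a, 10); expect_equal(out2$b, 90)
  expect_equal(out2$c, 10); expect_equal(out2$d, 890)
  expect_equal(exp(out2$log_or), 10 * 890 / (90 * 10), tolerance = 1e-12)
  expect_equal(out2$p, fisher_oracle_p(10, 90, 10, 890), tolerance = 1e-9)
})

test_that("Fisher p-values match enumeration for all margins up to 50", {
  set.seed(72)
  for (r in 1:50) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    cc <- sample(0:12, 1); d <- sample(0:12, 1)
    if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) next
    p_pkg <- fisher.test(matrix(c(a, b, cc, d), 2))$p.value
    expect_equal(p_pkg, fisher_oracle_p(a, b, cc, d), tolerance = 1e-9)
  }
})

test_that("enrichment is invariant to splitting an interval in two", {
  target <- tibble::tibble(chrom = "1", pos = seq(10L, 400L, by = 10L))
  bg <- tibble::tibble(chrom = "1", pos = seq(10L, 2000L, by = 10L))
  whole <- tibble::tibble(chrom = "1", start = 0L, end = 300L, label = "x")
  split <- tibble::tibble(chrom = "1", start = c(0L, 120L),
                          end = c(120L, 300L), label = "x")
  out_w <- suppressWarnings(fisher_enrichment(target, bg, whole))
  out_s <- suppressWarnings(fisher_enrichment(target, bg, split))
  expect_equal(out_w[c("a", "b", "c", "d", "log_or", "p")],
               out_s[c("a", "b", "c", "d", "log_or", "p")])
})

test_that("interval membership is half-open with 1-based point features", {
  iv <- tibble::tibble(chrom = "1", start = 100L, end = 200L, label = "x")
  # 1-based position 101 -> 0-based 100 = start: inside
  # 1-based position 200 -> 0-based 199 < 200: inside
  # 1-based position 201 -> 0-based 200 = end: outside
  feats <- tibble::tibble(chrom = "1", pos = c(100L, 101L, 200L, 201L))
  bg <- tibble::tibble(chrom = "1", pos = c(feats$pos, 5000L))
  out <- suppressWarnings(fisher_enrichment(feats, bg, iv))
  expect_equal(out$a, 2) # positions 101 and 200
})

test_that("degenerate all-inside annotation gets a continuity correction", {
  iv <- tibble::tibble(chrom = "1", start = 0L, end = 1e6L, label = "genome")
  target <- tibble::tibble(chrom = "1", pos = 1:10 * 10L)
  bg <- tibble::tibble(chrom = "1", pos = 1:50 * 10L)
  expect_warning(out <- fisher_enrichment(target, bg, iv), "continuity")
  expect_true(is.finite(out$log_or))
})

test_that("random-effects meta-analysis follows DerSimonian-Laird behaviour", {
  est <- tibble::tibble(log_or = c(0.7, 0.7, 0.7), se_log_or = 0.1,
                        tissue = c("blood", "colon", "lung"))
  out <- re_meta_analysis(est)
  expect_equal(out$log_or, 0.7, tolerance = 1e-12)
  expect_equal(out$tau2, 0)
  # a tissue with an enormous SE carries no weight
  est2 <- tibble::tibble(log_or = c(0.5, 0.6, 50), se_log_or = c(0.1, 0.1, 1e6))
  out2 <- suppressWarnings(re_meta_analysis(est2))
  out2_small <- re_meta_analysis(est2[1:2, ])
  expect_equal(out2$log_or, out2_small$log_or, tolerance = 1e-3)
  # pooled estimate stays inside the input range
  set.seed(73)
  for (r in 1:10) {
    e <- tibble::tibble(log_or = rnorm(4), se_log_or = runif(4, 0.05, 0.5))
    pooled <- re_meta_analysis(e)$log_or
    expect_gte(pooled, min(e$log_or) - 1e-12)
    expect_lte(pooled, max(e$log_or) + 1e-12)
  }
  expect_error(re_meta_analysis(tibble::tibble(log_or = 1, se_log_or = 0.1)),
               "at least 2")
  expect_error(re_meta_analysis(dplyr::mutate(est, se_log_or = 0)), "positive")
})

test_that("DL pooling matches the closed-form estimator", {
  est <- tibble::tibble(log_or = c(0.2, 0.8, 0.5), se_log_or = c(0.1, 0.2, 0.15))
  out <- re_meta_analysis(est)
  w <- 1 / est$se_log_or^2
  mu_fe <- sum(w * est$log_or) / sum(w)
  q <- sum(w * (est$log_or - mu_fe)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - 2) / cc)
  w_re <- 1 / (est$se_log_or^2 + tau2)
  expect_equal(out$tau2, tau2, tolerance = 1e-10)
  expect_equal(out$log_or, sum(w_re * est$log_or) / sum(w_re),
               tolerance = 1e-10)
  expect_equal(out$se, sqrt(1 / sum(w_re)), tolerance = 1e-10)
})
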
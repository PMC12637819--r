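# Shared fixtures, built in code at test time.

# small four-cell-type study with optional planted effects
make_study <- function(n_samples = 150, n_variants = 20, n_cpgs = 10,
                       effect_table = NULL, noise_sd = 0.05, seed = 11L,
                       dirichlet_alpha = c(5, 2, 1, 2)) {
  cfg <- simulation_config(n_samples = n_samples, n_variants = n_variants,
                           n_cpgs = n_cpgs, effect_table = effect_table,
                           noise_sd = noise_sd, seed = seed,
                           dirichlet_alpha = dirichlet_alpha)
  simulate_study(cfg)
}

# transformed response matrix for direct model fitting
int_mvalues <- function(beta) t(apply(beta_to_mvalue(beta), 1, rank_inverse_normal))

# independent hypergeometric-sum oracle for the two-sided Fisher test
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  support <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force coloc posterior over all causal-configuration pairs
coloc_oracle <- function(labf1, labf2, priors) {
  b1 <- exp(labf1); b2 <- exp(labf2)
  m <- length(b1)
  w <- c(h0 = 1, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (i in seq_len(m)) w["h1"] <- w["h1"] + priors$p1 * b1[i]
  for (j in seq_len(m)) w["h2"] <- w["h2"] + priors$p2 * b2[j]
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) w["h4"] <- w["h4"] + priors$p12 * b1[i] * b2[j]
    else w["h3"] <- w["h3"] + priors$p1 * priors$p2 * b1[i] * b2[j]
  }
  w / sum(w)
}
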
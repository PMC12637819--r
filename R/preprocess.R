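# Transformations, covariate construction and variant QC applied upstream of
# QTL mapping.

#' Convert beta values to M-values
#'
#' `M = log2(beta / (1 - beta))`, elementwise. Beta values must be strictly
#' inside (0, 1); clip upstream (see `beta_clip_eps` in
#' [simulation_config()]) before transforming.
#'
#' @param beta Numeric vector or matrix of methylation fractions in (0, 1).
#' @return Object of the same shape on the M-value scale.
#' @export
beta_to_mvalue <- function(beta) {
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE)) {
    abort("beta values at or beyond 0/1: clip to (eps, 1 - eps) upstream")
  }
  log2(beta / (1 - beta))
}

#' Rank-based inverse normal transform
#'
#' Replaces each value by `qnorm((rank - 0.5) / n)`; ties receive their
#' average rank. The transform is invariant to any monotone rescaling of the
#' input and is idempotent up to ties.
#'
#' @param x Numeric vector (length >= 2, finite, non-constant).
#' @return Transformed numeric vector with mean ~0 and SD ~1.
#' @export
rank_inverse_normal <- function(x) {
  assert_that(length(x) >= 2, "need at least two values")
  assert_that(all(is.finite(x)), "values must be finite")
  if (diff(range(x)) == 0) {
    abort("constant vector: ranks undefined for QTL transformation")
  }
  qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' k-nearest-neighbour imputation of missing methylation values
#'
#' Operates on rows (CpGs): a missing entry is replaced by the mean of the k
#' nearest rows, with distance measured as root mean squared difference over
#' the columns both rows observe, restricted to candidate rows that observe
#' the missing column.
#'
#' @param x Numeric matrix (CpG x sample) possibly containing `NA`.
#' @param k Number of neighbours (default 10).
#' @return Complete matrix of the same shape.
#' @export
impute_knn <- function(x, k = 10) {
  if (!anyNA(x)) return(x)
  miss_rows <- which(rowSums(is.na(x)) > 0)
  if (any(rowSums(!is.na(x)) == 0)) abort("row entirely missing: cannot impute")
  complete_cols <- !is.na(x)
  for (i in miss_rows) {
    cols_i <- complete_cols[i, ]
    for (jj in which(is.na(x[i, ]))) {
      cand <- which(complete_cols[, jj] & seq_len(nrow(x)) != i)
      if (length(cand) < k) {
        abort(sprintf("row %d has fewer than k complete neighbour rows", i))
      }
      shared <- complete_cols[cand, , drop = FALSE] &
        matrix(cols_i, nrow = length(cand), ncol = ncol(x), byrow = TRUE)
      d2 <- rowSums((x[cand, , drop = FALSE] -
                       matrix(x[i, ], nrow = length(cand), ncol = ncol(x),
                              byrow = TRUE))^2 * shared, na.rm = TRUE) /
        pmax(rowSums(shared), 1)
      nn <- cand[order(d2)[seq_len(k)]]
      x[i, jj] <- mean(x[nn, jj])
    }
  }
  x
}

#' Greedy LD pruning of variants
#'
#' Scans variants in position order per chromosome; a variant is dropped when
#' its squared correlation with any already-kept variant within the window
#' exceeds the threshold.
#'
#' @param genotypes `imqtl_geno` object.
#' @param r2_threshold Pairwise squared-correlation threshold (default 0.2).
#' @param window_bp Window size in bp (default 500 kb).
#' @return Logical keep-mask named by variant id.
#' @export
ld_prune <- function(genotypes, r2_threshold = 0.2, window_bp = 5e5) {
  v <- genotypes$variants
  keep <- rep(TRUE, nrow(v))
  names(keep) <- v$variant_id
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    idx <- idx[order(v$pos[idx])]
    kept <- integer()
    for (i in idx) {
      g_i <- genotypes$dosage[, i]
      if (var(g_i) == 0) { keep[i] <- FALSE; next }
      near <- kept[abs(v$pos[kept] - v$pos[i]) <= window_bp]
      drop <- FALSE
      for (jx in near) {
        r <- suppressWarnings(cor(g_i, genotypes$dosage[, jx]))
        if (is.finite(r) && r^2 > r2_threshold) { drop <- TRUE; break }
      }
      if (drop) keep[i] <- FALSE else kept <- c(kept, i)
    }
  }
  keep
}

#' Genetic principal components after LD pruning
#'
#' Prunes variants (pairwise r-squared threshold 0.2 in 500 kb windows), then
#' runs PCA on centred, variance-standardized dosages. The sign of each
#' component is fixed by making its largest-magnitude loading positive.
#'
#' @inheritParams ld_prune
#' @param n_pcs Number of score columns to return (default 5).
#' @return Tibble with `sample_id` and `pc1..pcN`, with the pruning mask in
#'   attribute `"pruned"`.
#' @export
compute_genetic_pcs <- function(genotypes, n_pcs = 5, r2_threshold = 0.2,
                                window_bp = 5e5) {
  assert_that(nrow(genotypes$dosage) >= n_pcs + 1,
              "need more samples than requested PCs")
  keep <- ld_prune(genotypes, r2_threshold, window_bp)
  if (sum(keep) < n_pcs) {
    abort(sprintf("only %d of %d variants survive LD pruning; need at least %d",
                  sum(keep), length(keep), n_pcs))
  }
  g <- genotypes$dosage[, keep, drop = FALSE]
  g <- scale(g)
  g[, attr(g, "scaled:scale") == 0] <- 0
  s <- svd(g, nu = n_pcs, nv = 0)
  scores <- s$u %*% diag(s$d[seq_len(n_pcs)], n_pcs)
  scores <- fix_pc_signs(scores)
  out <- as_tibble(setNames(as.data.frame(scores), paste0("pc", seq_len(n_pcs))))
  out <- dplyr::bind_cols(tibble(sample_id = rownames(genotypes$dosage)), out)
  attr(out, "pruned") <- keep
  out
}

# deterministic sign convention: largest |entry| of each column positive
fix_pc_signs <- function(scores) {
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  scores
}

#' Methylation principal components with elbow selection
#'
#' PCA on the CpG-centred matrix. The scree is rescaled to the unit square
#' and the elbow is the point with maximum perpendicular distance to the
#' line joining the first and last scree points; components before the
#' elbow are retained (L = elbow index - 1, at least 1). When no
#' pronounced elbow exists (maximum distance below `straightness`, as for
#' an isotropic-noise scree), a single component is retained.
#'
#' @param m M-value matrix, CpG x sample.
#' @param max_pcs Upper bound on the scree length examined.
#' @param straightness Minimum unit-square elbow distance below which the
#'   scree is treated as elbow-free (default 0.2).
#' @return List with `scores` (sample x L matrix), `n_pcs` (L) and
#'   `variances` (the scree).
#' @export
select_methylation_pcs <- function(m, max_pcs = NULL, straightness = 0.2) {
  n <- ncol(m)
  assert_that(n >= 3, "need at least 3 samples")
  x <- t(m - rowMeans(m)) # samples x CpGs, CpG-centred
  p <- min(n - 1, nrow(m), max_pcs %||% Inf)
  s <- svd(x, nu = p, nv = 0)
  ev <- (s$d^2 / (n - 1))[seq_len(p)]
  if (diff(range(ev)) < 1e-12 * max(ev, 1e-300)) {
    warn("degenerate scree (all eigenvalues equal); retaining 1 PC")
    l <- 1L
  } else {
    l <- elbow_point(ev, straightness)
  }
  scores <- s$u[, seq_len(l), drop = FALSE] %*% diag(s$d[seq_len(l)], l)
  scores <- fix_pc_signs(scores)
  rownames(scores) <- colnames(m)
  colnames(scores) <- paste0("mpc", seq_len(l))
  list(scores = scores, n_pcs = l, variances = ev)
}

# unit-square distance-to-line elbow on the scree; returns the number of
# components before the elbow (the first noise component sits at the elbow)
elbow_point <- function(ev, straightness = 0.2) {
  p <- length(ev)
  if (p <= 2) return(1L)
  x <- (seq_len(p) - 1) / (p - 1)
  y <- (ev - ev[p]) / (ev[1] - ev[p])
  d <- abs(x + y - 1) / sqrt(2) # distance to the (0,1)-(1,0) diagonal
  if (max(d) < straightness) return(1L)
  max(1L, as.integer(which.max(d)) - 1L)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional-on-allele-counts exact test: the p-value is the summed
#' probability of all heterozygote counts no more likely than the observed
#' one (no mid-p correction).
#'
#' @param n_aa,n_ab,n_bb Genotype counts (hom-ref, het, hom-alt).
#' @return Two-sided exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  hets <- seq(rare %% 2, rare, by = 2)
  # log-probability of each possible het count given allele counts
  lp <- lgamma(n + 1) - lgamma((rare - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma(n - (rare + hets) / 2 + 1) + hets * log(2) +
    lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  pr <- exp(lp - logsumexp(lp))
  p_obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

#' Variant quality-control filter
#'
#' Drops variants with any missingness among analysed samples, exact
#' Hardy-Weinberg p below `hwe_p`, or minor allele frequency at or below
#' `maf_min`. Filtering is order-independent.
#'
#' @param genotypes `imqtl_geno` object.
#' @param hwe_p HWE exact-test p-value threshold (default 1e-6).
#' @param maf_min MAF threshold; variants with MAF <= this are dropped
#'   (default 0.1).
#' @return List with `genotypes` (filtered) and `report` (tibble of counts
#'   per removal reason).
#' @export
filter_variants <- function(genotypes, hwe_p = 1e-6, maf_min = 0.1) {
  d <- genotypes$dosage
  miss <- colSums(is.na(d)) > 0
  f <- colMeans(d, na.rm = TRUE) / 2
  maf_fail <- pmin(f, 1 - f) <= maf_min
  hwe <- vapply(seq_len(ncol(d)), function(i) {
    g <- round(d[, i])
    hwe_exact_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                   sum(g == 2, na.rm = TRUE))
  }, numeric(1))
  hwe_fail <- hwe < hwe_p
  keep <- !(miss | maf_fail | hwe_fail)
  if (!any(keep)) warn("no variants survive QC")
  report <- tibble(
    reason = c("missingness", "maf", "hwe", "kept"),
    n = c(sum(miss), sum(maf_fail & !miss),
          sum(hwe_fail & !miss & !maf_fail), sum(keep))
  )
  out <- genotypes
  out$dosage <- d[, keep, drop = FALSE]
  out$variants <- genotypes$variants[keep, , drop = FALSE]
  list(genotypes = out, report = report)
}

#' Assemble the mapping covariate set
#'
#' Joins age/sex covariates with genetic and methylation PC scores into the
#' covariate table the interaction model consumes, dropping zero-variance
#' columns.
#'
#' @param covariates Tibble with `sample_id`, `age`, `sex`.
#' @param genetic_pcs Optional tibble from [compute_genetic_pcs()].
#' @param methylation_pcs Optional score matrix from
#'   [select_methylation_pcs()].
#' @return Tibble with `sample_id` and numeric covariate columns, no missing
#'   values.
#' @export
build_covariates <- function(covariates, genetic_pcs = NULL,
                             methylation_pcs = NULL) {
  out <- as_tibble(covariates)
  if (!is.null(genetic_pcs)) out <- left_join(out, genetic_pcs, by = "sample_id")
  if (!is.null(methylation_pcs)) {
    mp <- as_tibble(methylation_pcs, rownames = "sample_id")
    out <- left_join(out, mp, by = "sample_id")
  }
  if (anyNA(out)) abort("missing values in covariate set after construction")
  num <- setdiff(names(out), "sample_id")
  keep <- vapply(out[num], function(x) var(x) > 0, logical(1))
  if (any(!keep)) {
    inform(sprintf("dropping zero-variance covariates: %s",
                   paste(num[!keep], collapse = ", ")))
  }
  out[c("sample_id", num[keep])]
}
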
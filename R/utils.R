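# Internal helpers shared across modules.

#' Derive a child seed from a global seed
#'
#' A single integer seed fans out deterministically to per-operation child
#' seeds so that individual pipeline stages can be re-run in isolation while
#' the whole study stays reproducible. Child seeds stay below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param index Non-negative integer identifying the consuming operation.
#' @return An integer seed.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483629 # largest prime < 2^31
  as.integer(((abs(seed) %% m) * 48271 + index) %% m)
}

# Dirichlet draws via normalized gamma variates; rows sum to one exactly up
# to floating renormalization.
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  # guard against all-zero rows at tiny alpha (gamma underflow)
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, ] <- matrix(rgamma(sum(zero) * k, shape = rep(alpha, each = sum(zero))) + 1e-300, nrow = sum(zero))
  x / rowSums(x)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

sample_ids <- function(n) sprintf("S%04d", seq_len(n))
variant_ids <- function(chrom, pos) sprintf("chr%s_%d", chrom, pos)
cpg_ids <- function(n) sprintf("cg%07d", seq_len(n))

assert_that <- function(ok, msg) if (!isTRUE(ok)) abort(msg)
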
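# Cell-type differential-methylation EWAS, annotation enrichment of mapped
# variants and CpGs, and cross-tissue random-effects meta-analysis.

#' EWAS of methylation on a cell type's proportion
#'
#' Per CpG, OLS of the transformed methylation value on the cell type's
#' proportion plus covariates; differentially methylated sites (DMS) are
#' CpGs passing BH-FDR below the threshold. The design is shared across
#' CpGs so a single factorization serves the whole scan.
#'
#' @param meth CpG x sample matrix of transformed methylation values.
#' @param prop Proportion vector of the cell type.
#' @param covars Optional covariate matrix.
#' @param fdr_threshold BH-FDR cutoff defining DMS (default 0.05).
#' @return Tibble with `cpg_id`, `estimate`, `se`, `p`, `fdr`, `is_dms`.
#' @export
ewas_cell_proportion_dms <- function(meth, prop, covars = NULL,
                                     fdr_threshold = 0.05) {
  assert_that(var(prop) > 0, "constant proportion vector")
  x <- cbind(intercept = 1, prop = prop)
  if (!is.null(covars)) x <- cbind(x, as.matrix(covars))
  qx <- qr(x)
  assert_that(qx$rank == ncol(x), "rank-deficient EWAS design")
  n <- ncol(meth); p <- ncol(x)
  cf <- qr.coef(qx, t(meth))              # p x CpGs
  res <- t(meth) - x %*% cf
  sigma2 <- colSums(res^2) / (n - p)
  inv_pp <- chol2inv(qr.R(qx))[2, 2]      # (X'X)^-1 for the proportion term
  se <- sqrt(sigma2 * inv_pp)
  est <- cf["prop", ]
  pval <- 2 * pt(abs(est / se), n - p, lower.tail = FALSE)
  fdr <- p.adjust(pval, method = "BH")
  tibble(cpg_id = rownames(meth), estimate = est, se = se, p = pval,
         fdr = fdr, is_dms = fdr < fdr_threshold)
}

#' Fraction of a CpG set falling in cell-type DMS
#'
#' @param cpg_sets Named list of character vectors of CpG ids (e.g. imQTL
#'   CpGs, mQTL CpGs).
#' @param dms_union Character vector: the union of DMS over all cell types.
#' @param background Character vector of all analysed CpGs.
#' @return Tibble with one row per set plus the background, giving the
#'   fraction of the set intersecting the DMS union.
#' @export
proportion_in_dms <- function(cpg_sets, dms_union, background) {
  assert_that(length(background) > 0, "empty background CpG set")
  sets <- c(cpg_sets, list(background = background))
  map_dfr(names(sets), function(nm) {
    s <- sets[[nm]]
    tibble(set = nm, n = length(s),
           fraction_in_dms = if (length(s)) mean(s %in% dms_union) else NA_real_)
  })
}

#' Read a BED file of annotation intervals
#'
#' Three or more tab-separated columns; column 4, when present, is the
#' interval label. Coordinates are kept 0-based half-open as in the file.
#'
#' @param path File path.
#' @param label Annotation name applied to all intervals (defaults to the
#'   file name); per-interval labels from column 4 are kept in `name`.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `label`, sorted per
#'   chromosome.
#' @export
read_bed <- function(path, label = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  assert_that(ncol(raw) >= 3, "BED needs at least 3 columns")
  out <- tibble(chrom = as.character(raw[[1]]), start = as.integer(raw[[2]]),
                end = as.integer(raw[[3]]),
                name = if (ncol(raw) >= 4) as.character(raw[[4]]) else NA_character_,
                label = label %||% basename(path))
  assert_that(all(out$start < out$end), "BED intervals must satisfy start < end")
  arrange(out, .data$chrom, .data$start)
}

# Half-open point-in-interval membership: a 1-based feature position pos is
# inside a 0-based half-open interval [start, end) iff start <= pos - 1 < end.
points_in_intervals <- function(chrom, pos, intervals) {
  inside <- logical(length(pos))
  pos0 <- pos - 1L
  for (chr in unique(chrom)) {
    iv <- intervals[intervals$chrom == chr, , drop = FALSE]
    if (nrow(iv) == 0) next
    sel <- chrom == chr
    # flatten to a sorted union of disjoint intervals, then binary search
    iv <- iv[order(iv$start), ]
    merged_start <- iv$start[1]; merged_end <- iv$end[1]
    starts <- ends <- numeric(0)
    for (r in seq_len(nrow(iv))[-1]) {
      if (iv$start[r] <= merged_end) {
        merged_end <- max(merged_end, iv$end[r])
      } else {
        starts <- c(starts, merged_start); ends <- c(ends, merged_end)
        merged_start <- iv$start[r]; merged_end <- iv$end[r]
      }
    }
    starts <- c(starts, merged_start); ends <- c(ends, merged_end)
    idx <- findInterval(pos0[sel], starts)
    inside[sel] <- idx >= 1 & pos0[sel] < ends[pmax(idx, 1)]
  }
  inside
}

#' Fisher enrichment of target features in genomic annotations
#'
#' For each annotation label, a 2x2 table (inside/outside annotation by
#' target/background-minus-target) is tested with a two-sided Fisher exact
#' test. The log odds ratio uses the sample odds ratio, with a 0.5
#' continuity (Haldane-Anscombe) correction applied to every cell when any
#' cell is zero; its Woolf standard error is reported for meta-analysis.
#'
#' @param target Tibble of features with `chrom`, `pos` (1-based single-base
#'   positions: variant positions or CpG coordinates). Must be a strict
#'   subset of `background`.
#' @param background Tibble of the reference feature set (same columns).
#' @param annotations Tibble of intervals (`chrom`, `start`, `end`,
#'   `label`), 0-based half-open, e.g. from [read_bed()].
#' @param tissue Optional tissue tag copied to the output.
#' @return Tibble with one row per annotation label: counts `a` (target in),
#'   `b` (target out), `c` (rest in), `d` (rest out), `log_or`, `se_log_or`,
#'   `p`, `tissue`.
#' @export
fisher_enrichment <- function(target, background, annotations,
                              tissue = NA_character_) {
  key <- function(x) paste(x$chrom, x$pos)
  tk <- key(target); bk <- key(background)
  assert_that(all(tk %in% bk), "target must be a subset of the background")
  assert_that(length(setdiff(bk, tk)) > 0,
              "target equals background: enrichment undefined")
  rest <- background[!(bk %in% tk), , drop = FALSE]
  map_dfr(unique(annotations$label), function(lab) {
    iv <- annotations[annotations$label == lab, , drop = FALSE]
    a <- sum(points_in_intervals(target$chrom, target$pos, iv))
    b <- nrow(target) - a
    cc <- sum(points_in_intervals(rest$chrom, rest$pos, iv))
    d <- nrow(rest) - cc
    p <- fisher.test(matrix(c(a, b, cc, d), 2))$p.value
    cells <- c(a, b, cc, d)
    if (any(cells == 0)) {
      warn(sprintf("annotation '%s': zero cell; applying 0.5 continuity correction",
                   lab))
      cells <- cells + 0.5
    }
    log_or <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
    tibble(label = lab, a = a, b = b, c = cc, d = d, log_or = log_or,
           se_log_or = sqrt(sum(1 / cells)), p = p, tissue = tissue)
  })
}

#' Random-effects meta-analysis of log odds ratios
#'
#' DerSimonian-Laird random-effects pooling of per-tissue log odds ratios:
#' `tau^2 = max(0, (Q - df) / C)` with inverse-variance weights
#' `1 / (se^2 + tau^2)`.
#'
#' @param estimates Tibble with `log_or`, `se_log_or` and optionally
#'   `tissue`.
#' @return One-row tibble with pooled `log_or`, `se`, `p`, `tau2`, `q` and
#'   `n_tissues`.
#' @export
re_meta_analysis <- function(estimates) {
  assert_that(nrow(estimates) >= 2, "need at least 2 tissues")
  assert_that(all(estimates$se_log_or > 0), "standard errors must be positive")
  fit <- metafor::rma(yi = estimates$log_or, sei = estimates$se_log_or,
                      method = "DL")
  tibble(log_or = as.numeric(fit$beta), se = fit$se, p = fit$pval,
         tau2 = fit$tau2, q = fit$QE, n_tissues = nrow(estimates))
}
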
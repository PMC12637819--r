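# Reference-based cell-type deconvolution: panel construction from
# sorted-cell methylomes, in-silico validation, and robust-partial-
# correlation estimation of proportions from bulk beta values.

#' Panel-construction configuration
#'
#' Selection thresholds for cell-type-discriminating CpGs (DMCs). The
#' defaults reproduce a generic four-cell-type panel: a stringent FDR below
#' 0.001, hypomethylation in the target cell type, and an absolute beta
#' difference above a per-type threshold (0.9 immune, 0.8 epithelial, 0.81
#' fibroblast, 0.715 endothelial), each at or above a global floor of 0.7
#' that keeps differences biological rather than technical.
#'
#' @param fdr_threshold BH-FDR cutoff for the moderated one-vs-rest test.
#' @param delta_thresholds Named per-cell-type absolute beta-difference
#'   thresholds; unnamed types fall back to `delta_floor`.
#' @param delta_floor Global minimum beta difference.
#' @return List of class `panel_config`.
#' @export
panel_config <- function(fdr_threshold = 0.001,
                         delta_thresholds = c(immune = 0.9, epithelial = 0.8,
                                              fibroblast = 0.81,
                                              endothelial = 0.715),
                         delta_floor = 0.7) {
  assert_that(all(delta_thresholds > 0 & delta_thresholds <= 1),
              "delta thresholds must lie in (0, 1]")
  assert_that(delta_floor <= min(delta_thresholds),
              "delta_floor must not exceed any per-type threshold")
  structure(list(fdr_threshold = fdr_threshold,
                 delta_thresholds = delta_thresholds,
                 delta_floor = delta_floor),
            class = "panel_config")
}

#' Build a cell-type deconvolution reference panel
#'
#' For each cell type, a one-vs-rest moderated t-test (empirical-Bayes
#' variance shrinkage via limma) is run per CpG on the beta scale. A CpG is
#' selected as a DMC for the type when (i) its BH-FDR is below the
#' threshold, (ii) it is hypomethylated in the target type relative to the
#' pooled mean of the remaining types, and (iii) the absolute mean
#' difference exceeds the type's delta threshold. CpGs passing for several
#' types are assigned to the type with the largest difference. The centroid
#' is the per-type mean beta over the union of selected DMCs.
#'
#' @param beta CpG x sample beta matrix of sorted-cell profiles.
#' @param labels Cell-type label per sample (column).
#' @param config A [panel_config()].
#' @return Tibble of class `imqtl_panel`: `cpg_id`, one centroid column per
#'   cell type, `target_type`, `delta`, `fdr`.
#' @export
build_reference_panel <- function(beta, labels, config = panel_config()) {
  cell_types <- sort(unique(labels))
  assert_that(all(table(labels) >= 2), "need >= 2 samples per cell type")
  sel <- list()
  for (ct in cell_types) {
    design <- cbind(Intercept = 1, target = as.numeric(labels == ct))
    fit <- limma::eBayes(limma::lmFit(beta, design))
    fdr <- p.adjust(fit$p.value[, "target"], method = "BH")
    mean_target <- rowMeans(beta[, labels == ct, drop = FALSE])
    mean_rest <- rowMeans(beta[, labels != ct, drop = FALSE])
    delta <- mean_rest - mean_target # positive = hypomethylated in target
    thr <- config$delta_thresholds[ct]
    if (is.na(thr)) thr <- config$delta_floor
    pass <- fdr < config$fdr_threshold & mean_target < mean_rest &
      abs(delta) > thr
    if (!any(pass)) {
      abort(sprintf(
        "no DMCs selected for cell type '%s' (FDR < %g, hypomethylated, |delta| > %g)",
        ct, config$fdr_threshold, thr))
    }
    sel[[ct]] <- tibble(cpg_id = rownames(beta)[pass], target_type = ct,
                        delta = unname(delta[pass]), fdr = unname(fdr[pass]))
  }
  dmcs <- bind_rows(sel)
  # unique assignment: keep the strongest claim per CpG
  dmcs <- dmcs |>
    group_by(.data$cpg_id) |>
    slice_min(order_by = -.data$delta, n = 1, with_ties = FALSE) |>
    ungroup()
  centroid <- vapply(cell_types, function(ct) {
    rowMeans(beta[dmcs$cpg_id, labels == ct, drop = FALSE])
  }, numeric(nrow(dmcs)))
  out <- dplyr::bind_cols(tibble(cpg_id = dmcs$cpg_id),
                          as_tibble(centroid)) |>
    mutate(target_type = dmcs$target_type, delta = dmcs$delta,
           fdr = dmcs$fdr) |>
    arrange(.data$cpg_id)
  class(out) <- c("imqtl_panel", class(out))
  attr(out, "cell_types") <- cell_types
  out
}

panel_centroid <- function(panel) {
  m <- as.matrix(panel[attr(panel, "cell_types")])
  rownames(m) <- panel$cpg_id
  m
}

#' Estimate cell-type proportions by robust partial correlation
#'
#' Each bulk sample's beta values at panel CpGs are regressed on the
#' centroid columns by robust linear regression (Huber loss, tuning constant
#' 1.345, iteratively reweighted least squares, at most `max_iter`
#' iterations, no intercept). Negative coefficients are truncated to zero
#' and the remainder renormalized to the probability simplex.
#'
#' @param bulk_beta CpG x sample beta matrix.
#' @param panel `imqtl_panel` from [build_reference_panel()].
#' @param max_iter Maximum IRLS iterations (default 500).
#' @return Tibble with `sample_id`, one column per cell type, and a
#'   `converged` diagnostic column; rows sum to 1.
#' @export
rpc_deconvolute <- function(bulk_beta, panel, max_iter = 500) {
  x <- panel_centroid(panel)
  shared <- intersect(rownames(x), rownames(bulk_beta))
  assert_that(length(shared) >= 1, "no panel CpGs present in the bulk matrix")
  if (length(shared) < 0.5 * nrow(x)) {
    warn(sprintf("only %d of %d panel CpGs present in the bulk matrix",
                 length(shared), nrow(x)))
  }
  x <- x[shared, , drop = FALSE]
  if (qr(x)$rank < ncol(x)) {
    abort("centroid matrix is singular: collinear cell types")
  }
  res <- map_dfr(seq_len(ncol(bulk_beta)), function(i) {
    y <- bulk_beta[shared, i]
    fit <- suppressWarnings(
      MASS::rlm(x, y, psi = MASS::psi.huber, k = 1.345, maxit = max_iter))
    cf <- pmax(coef(fit), 0)
    if (sum(cf) == 0) {
      warn(sprintf("all-nonpositive coefficients for sample %d; returning uniform",
                   i))
      cf <- rep(1 / length(cf), length(cf))
    }
    conv <- isTRUE(fit$converged)
    if (!conv) warn(sprintf("IRLS did not converge for sample %d", i))
    tibble(sample_id = colnames(bulk_beta)[i] %||% sprintf("S%04d", i),
           !!!setNames(as.list(cf / sum(cf)), colnames(x)),
           converged = conv)
  })
  res
}

#' Validate a reference panel on in-silico mixtures
#'
#' Repeatedly draws one held-out sorted profile per cell type, mixes them
#' with flat-Dirichlet weights (random weights summing to one), optionally
#' adds beta-scale noise, deconvolutes the mixture with the panel, and
#' compares estimated with true fractions.
#'
#' @param panel `imqtl_panel`.
#' @param holdout_beta CpG x sample matrix of held-out sorted profiles.
#' @param holdout_labels Cell-type label per held-out column.
#' @param n_mixtures Number of mixtures (default 500; fewer than 10 warns).
#' @param noise_sd Beta-scale noise added to each mixture (default 0).
#' @param seed Integer seed.
#' @return Tibble of class `panel_validation`: `cell_type`, `pearson_r`,
#'   `rmse`; per-mixture true/estimated fractions in attribute
#'   `"mixtures"`.
#' @export
validate_panel_insilico <- function(panel, holdout_beta, holdout_labels,
                                    n_mixtures = 500, noise_sd = 0,
                                    seed = 1L) {
  cell_types <- attr(panel, "cell_types")
  assert_that(all(cell_types %in% holdout_labels),
              "need at least one held-out sample per panel cell type")
  if (n_mixtures < 10) warn("fewer than 10 mixtures: correlations unstable")
  set.seed(seed)
  k <- length(cell_types)
  idx <- lapply(cell_types, function(ct) which(holdout_labels == ct))
  w <- rdirichlet_mat(n_mixtures, rep(1, k))
  mixed <- vapply(seq_len(n_mixtures), function(m) {
    cols <- vapply(idx, function(ii) ii[sample.int(length(ii), 1)], integer(1))
    prof <- holdout_beta[, cols, drop = FALSE] %*% w[m, ]
    if (noise_sd > 0) prof <- prof + rnorm(nrow(prof), 0, noise_sd)
    pmin(pmax(prof, 1e-3), 1 - 1e-3)
  }, numeric(nrow(holdout_beta)))
  rownames(mixed) <- rownames(holdout_beta)
  colnames(mixed) <- sprintf("mix%03d", seq_len(n_mixtures))
  est <- rpc_deconvolute(mixed, panel)
  est_m <- as.matrix(est[cell_types])
  report <- tibble(
    cell_type = cell_types,
    pearson_r = vapply(seq_len(k), function(j) cor(w[, j], est_m[, j]),
                       numeric(1)),
    rmse = vapply(seq_len(k), function(j) sqrt(mean((w[, j] - est_m[, j])^2)),
                  numeric(1))
  )
  attr(report, "mixtures") <- list(true = w, estimated = est_m)
  class(report) <- c("panel_validation", class(report))
  report
}

#' Exclude zero-inflated cell types
#'
#' Cell types for which more than `threshold` of individuals have an exactly
#' zero estimated proportion are excluded from downstream mapping (strictly
#' greater than the threshold; a type at exactly 50% zeros is retained).
#'
#' @param proportions Proportion tibble from [rpc_deconvolute()].
#' @param threshold Exclusion threshold on the zero fraction (default 0.5).
#' @return List with `retained` (character), `excluded` (character) and
#'   `report` (tibble of zero fractions).
#' @export
zero_inflation_filter <- function(proportions, threshold = 0.5) {
  cells <- setdiff(names(proportions), c("sample_id", "converged"))
  zero_frac <- vapply(proportions[cells], function(x) mean(x == 0), numeric(1))
  excluded <- cells[zero_frac > threshold]
  retained <- setdiff(cells, excluded)
  if (length(retained) == 0) abort("all cell types excluded as zero-inflated")
  list(retained = retained, excluded = excluded,
       report = tibble(cell_type = cells, zero_fraction = zero_frac,
                       excluded = cells %in% excluded))
}
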
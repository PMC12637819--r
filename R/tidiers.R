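# broom-style tidy()/glance() methods and print methods for result objects.

#' Tidy an interaction or marginal scan
#'
#' @param x `imqtl_scan` object.
#' @param ... Unused.
#' @return The full association tibble (one row per variant-CpG pair fit).
#' @method tidy imqtl_scan
#' @export
tidy.imqtl_scan <- function(x, ...) x$associations

#' One-line summary of a scan
#'
#' @param x `imqtl_scan` object.
#' @param ... Unused.
#' @return One-row tibble: modeled term, cell type, numbers of pairs, CpGs
#'   tested, skipped CpGs and significant imQTLs.
#' @method glance imqtl_scan
#' @export
glance.imqtl_scan <- function(x, ...) {
  tibble(cell_type = x$meta$cell_type, term = x$meta$term,
         n_pairs = nrow(x$associations),
         n_cpgs_tested = x$meta$n_cpgs_tested,
         n_cpgs_skipped = nrow(x$skipped),
         n_significant = sum(x$leads$significant))
}

#' @export
print.imqtl_scan <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<imqtl_scan> %s: %d pair fits across %d CpGs, %d significant lead pair(s)\n",
              g$cell_type, g$n_pairs, g$n_cpgs_tested, g$n_significant))
  invisible(x)
}

#' Tidy a reference panel
#'
#' @param x `imqtl_panel` object.
#' @param ... Unused.
#' @return Plain tibble of DMCs with centroid columns and provenance.
#' @method tidy imqtl_panel
#' @export
tidy.imqtl_panel <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "imqtl_panel")
  attr(out, "cell_types") <- NULL
  out
}

#' One-line summary of a reference panel
#'
#' @param x `imqtl_panel` object.
#' @param ... Unused.
#' @return One-row tibble with the total DMC count and per-type counts.
#' @method glance imqtl_panel
#' @export
glance.imqtl_panel <- function(x, ...) {
  counts <- table(x$target_type)
  dplyr::bind_cols(tibble(n_dmcs = nrow(x)),
                   as_tibble(as.list(counts)))
}

#' @export
print.imqtl_panel <- function(x, ...) {
  cat(sprintf("<imqtl_panel> %d DMCs over %d cell types (%s)\n", nrow(x),
              length(attr(x, "cell_types")),
              paste(sprintf("%s: %d", names(table(x$target_type)),
                            table(x$target_type)), collapse = ", ")))
  print(tidy(x))
  invisible(x)
}

#' Tidy a sharing matrix into long format
#'
#' @param x `imqtl_sharing` object.
#' @param ... Unused.
#' @return Tibble with `reference` (cell type a), `other` (cell type b) and
#'   `sharing`.
#' @method tidy imqtl_sharing
#' @export
tidy.imqtl_sharing <- function(x, ...) {
  s <- x$sharing
  tibble(reference = rep(rownames(s), times = ncol(s)),
         other = rep(colnames(s), each = nrow(s)),
         sharing = as.vector(s))
}

#' One-line summary of a validation report
#'
#' @param x `panel_validation` object.
#' @param ... Unused.
#' @return One-row tibble with the worst per-cell-type correlation and RMSE.
#' @method glance panel_validation
#' @export
glance.panel_validation <- function(x, ...) {
  tibble(min_pearson_r = min(x$pearson_r), max_rmse = max(x$rmse),
         n_cell_types = nrow(x))
}
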
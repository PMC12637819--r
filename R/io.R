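# Plain-text readers and writers for the pipeline's tabular formats.
# readr handles gzip transparently in both directions, so every path may
# carry a .gz suffix.

#' Write genotypes as a dosage TSV
#'
#' One row per variant: `variant_id`, `chrom`, `pos`, `ref`, `alt`, then one
#' dosage column per sample.
#'
#' @param genotypes `imqtl_geno` object.
#' @param path Output path (optionally .gz).
#' @export
write_dosage_tsv <- function(genotypes, path) {
  out <- dplyr::bind_cols(genotypes$variants[c("variant_id", "chrom", "pos",
                                               "ref", "alt")],
                          as_tibble(t(genotypes$dosage)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read genotypes from a dosage TSV
#'
#' @param path Path written by [write_dosage_tsv()].
#' @return `imqtl_geno` object.
#' @export
read_dosage_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt")
  assert_that(all(meta_cols %in% names(raw)), "missing variant metadata columns")
  samples <- setdiff(names(raw), meta_cols)
  dosage <- t(as.matrix(raw[samples]))
  colnames(dosage) <- raw$variant_id
  f <- colMeans(dosage) / 2
  structure(list(dosage = dosage,
                 variants = mutate(raw[meta_cols],
                                   chrom = as.character(.data$chrom),
                                   maf = pmin(f, 1 - f))),
            class = "imqtl_geno")
}

#' Write genotypes as a minimal VCFv4.2
#'
#' Hard-call dosages become unphased GT genotypes (0/0, 0/1, 1/1).
#'
#' @param genotypes `imqtl_geno` object.
#' @param path Output path (optionally .gz).
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  gt <- c("0/0", "0/1", "1/1")[round(t(genotypes$dosage)) + 1]
  gt <- matrix(gt, nrow = nrow(v))
  body <- cbind(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
                "GT", gt)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(genotypes$dosage)),
                     collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Counts alternate alleles in the GT field; missing INFO fields are
#' tolerated. Genotypes with missing calls become `NA` dosages.
#'
#' @param path VCF path (optionally gzipped).
#' @return `imqtl_geno` object.
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | grepl("\\.", x), NA_real_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) sum(a == "1"), numeric(1)))
  }
  dosage <- t(apply(gt, 2, count_alt))
  dosage <- matrix(as.numeric(dosage), nrow = ncol(gt),
                   dimnames = list(colnames(gt), rownames(gt)))
  fix <- vcfR::getFIX(v)
  f <- colMeans(dosage, na.rm = TRUE) / 2
  structure(list(dosage = dosage,
                 variants = tibble(variant_id = fix[, "ID"],
                                   chrom = fix[, "CHROM"],
                                   pos = as.integer(fix[, "POS"]),
                                   ref = fix[, "REF"], alt = fix[, "ALT"],
                                   maf = pmin(f, 1 - f))),
            class = "imqtl_geno")
}

#' Write a methylation matrix as TSV (rows are CpGs)
#'
#' @param meth CpG x sample matrix.
#' @param path Output path.
#' @export
write_methylation_tsv <- function(meth, path) {
  out <- dplyr::bind_cols(tibble(cpg_id = rownames(meth)), as_tibble(meth))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a methylation matrix from TSV
#'
#' @param path Path written by [write_methylation_tsv()].
#' @return CpG x sample numeric matrix.
#' @export
read_methylation_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(raw[setdiff(names(raw), "cpg_id")])
  rownames(m) <- raw$cpg_id
  m
}

#' Write or read a reference panel TSV
#'
#' Columns: `cpg_id`, one centroid column per cell type, `target_type`,
#' `delta`, `fdr`.
#'
#' @param panel `imqtl_panel` object.
#' @param path File path.
#' @export
write_panel_tsv <- function(panel, path) {
  readr::write_tsv(as_tibble(panel), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @return `read_panel_tsv()` returns an `imqtl_panel`.
#' @export
read_panel_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cells <- setdiff(names(out), c("cpg_id", "target_type", "delta", "fdr"))
  class(out) <- c("imqtl_panel", class(out))
  attr(out, "cell_types") <- cells
  out
}

#' Read per-variant association summary statistics
#'
#' Expects columns `variant_id`, `chrom`, `pos`, `ref`, `alt` and either
#' `beta` + `se`, or `p` + `maf` + `n` from which the standard error is
#' reconstructed as `1 / sqrt(2 maf (1 - maf) n)` (the quantitative-trait
#' approximation) and the effect as `|z| * se` signed by `beta` when a beta
#' column is present (unsigned otherwise).
#'
#' @param path TSV path.
#' @return Tibble ready for [coloc_enumerate()].
#' @export
read_summary_stats <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_that("variant_id" %in% names(raw), "variant_id column required")
  if (!all(c("beta", "se") %in% names(raw))) {
    assert_that(all(c("p", "maf", "n") %in% names(raw)),
                "need beta+se or p+maf+n columns")
    se <- 1 / sqrt(2 * raw$maf * (1 - raw$maf) * raw$n)
    z <- qnorm(raw$p / 2, lower.tail = FALSE)
    sgn <- if ("beta" %in% names(raw)) sign(raw$beta) else 1
    raw$se <- se
    raw$beta <- sgn * z * se
  }
  raw
}

#' Write the planted-truth table of a simulated study
#'
#' @param sim `imqtl_sim` object.
#' @param path Output path.
#' @export
write_truth_tsv <- function(sim, path) {
  readr::write_tsv(sim$truth, path, progress = FALSE)
  invisible(path)
}
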
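## Sample- and gene-level expression filters and TMM-normalized log2-CPM,
## producing eQTL-ready matrices. Thresholds are strict inequalities as
## printed ("TPM >0.50", "counts >2 / >1"); "at least 20% of the samples"
## uses ceiling(0.20 * n).

#' Filtering configuration
#'
#' Defaults follow the two-step filter used for eQTL-ready matrices:
#' genes must show TPM > 0.50 in at least 20% of samples, and raw counts
#' above a biotype-specific threshold (> 2 for protein-coding, > 1 for
#' non-coding) in at least 20% of samples; samples with fewer than one
#' million reads assigned to genes are excluded.
#'
#' @param tpm_threshold TPM cut (strict `>`), default 0.50.
#' @param tpm_fraction fraction of samples that must pass, default 0.20.
#' @param count_threshold_pcg count cut for protein-coding genes, default 2.
#' @param count_threshold_lnc count cut for non-coding genes, default 1.
#' @param count_fraction fraction of samples for the count rule, default 0.20.
#' @param min_assigned_reads minimum column sum for a sample to be kept,
#'   default 1e6 (strict `<` drops).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(tpm_threshold = 0.50, tpm_fraction = 0.20,
                          count_threshold_pcg = 2L, count_threshold_lnc = 1L,
                          count_fraction = 0.20, min_assigned_reads = 1e6) {
  stopifnot(tpm_fraction > 0, tpm_fraction <= 1,
            count_fraction > 0, count_fraction <= 1,
            tpm_threshold >= 0, count_threshold_pcg >= 0,
            count_threshold_lnc >= 0, min_assigned_reads >= 0)
  structure(list(tpm_threshold = tpm_threshold, tpm_fraction = tpm_fraction,
                 count_threshold_pcg = count_threshold_pcg,
                 count_threshold_lnc = count_threshold_lnc,
                 count_fraction = count_fraction,
                 min_assigned_reads = min_assigned_reads),
            class = "filter_config")
}

#' Drop samples with too few reads assigned to genes
#'
#' A sample is removed when its column sum is strictly below
#' `cfg$min_assigned_reads`; a sum of exactly the threshold is kept.
#'
#' @param counts expression_matrix of raw counts.
#' @param cfg filter_config.
#' @return list with `counts` (filtered expression_matrix) and `dropped`
#'   (character vector of removed sample IDs).
#' @export
filter_samples <- function(counts, cfg = filter_config()) {
  sums <- colSums(counts$values)
  drop <- sums < cfg$min_assigned_reads
  if (all(drop)) stop("all samples fall below min_assigned_reads")
  out <- counts
  out$values <- counts$values[, !drop, drop = FALSE]
  out$sample_meta <- counts$sample_meta[!drop, ]
  list(counts = out, dropped = colnames(counts$values)[drop])
}

#' Gene keep-list from the two-step TPM / count filter
#'
#' A gene is kept iff it has TPM strictly above `tpm_threshold` in at least
#' `ceiling(tpm_fraction * n)` samples AND raw counts strictly above its
#' biotype threshold (protein_coding: `count_threshold_pcg`; everything
#' else: `count_threshold_lnc`) in at least `ceiling(count_fraction * n)`
#' samples.
#'
#' @param counts expression_matrix of raw counts.
#' @param tpm expression_matrix of TPM values over the same genes/samples.
#' @param cfg filter_config.
#' @return character vector of kept gene IDs.
#' @export
filter_genes <- function(counts, tpm, cfg = filter_config()) {
  stopifnot(identical(rownames(counts$values), rownames(tpm$values)),
            identical(colnames(counts$values), colnames(tpm$values)))
  bio <- counts$gene_meta$biotype
  if (is.null(bio) || anyNA(bio)) stop("gene missing biotype")
  n <- ncol(counts$values)
  need_tpm <- ceiling(cfg$tpm_fraction * n)
  need_cnt <- ceiling(cfg$count_fraction * n)
  thr <- ifelse(bio == "protein_coding", cfg$count_threshold_pcg,
                cfg$count_threshold_lnc)
  pass_tpm <- rowSums(tpm$values > cfg$tpm_threshold) >= need_tpm
  pass_cnt <- rowSums(counts$values > thr) >= need_cnt
  rownames(counts$values)[pass_tpm & pass_cnt]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors between samples, computed with
#' edgeR's implementation: the reference sample is the one whose upper
#' quartile of CPM is closest to the mean upper quartile; per sample, genes
#' zero in either library are excluded, log ratios (M) and mean log
#' abundances (A) are doubly trimmed, and the factor is two to the
#' precision-weighted trimmed mean of M. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param counts expression_matrix of raw counts (>= 2 samples).
#' @param trim_m two-sided trim fraction on M values, default 0.30.
#' @param trim_a two-sided trim fraction on A values, default 0.05.
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  v <- counts$values
  if (ncol(v) < 2) stop("TMM needs at least two samples")
  if (any(colSums(v) == 0)) stop("sample with all-zero counts")
  f <- edgeR::calcNormFactors(v, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  stats::setNames(as.numeric(f), colnames(v))
}

#' TMM-adjusted log2 counts per million
#'
#' Effective library size = column sum x TMM factor;
#' `log2cpm = log2((count + 0.5) / (effective size + 1) * 1e6)`.
#'
#' @param counts expression_matrix of raw counts.
#' @param factors per-sample TMM factors (from [tmm_factors()]).
#' @return list of class `normalized_matrix` with `log2cpm` (genes x
#'   samples) and `tmm_factors`.
#' @export
log2_cpm <- function(counts, factors = tmm_factors(counts)) {
  v <- counts$values
  stopifnot(length(factors) == ncol(v))
  eff <- colSums(v) * factors
  lc <- log2(sweep(v + 0.5, 2, eff + 1, "/") * 1e6)
  structure(list(log2cpm = lc, tmm_factors = factors),
            class = "normalized_matrix")
}

#' Alternative preset for co-expression pre-filtering
#'
#' Keeps genes with log2-CPM strictly above `threshold` in at least
#' `fraction` of samples — the looser pre-filter used ahead of network
#' construction (the network analysis itself is out of scope here).
#'
#' @param norm normalized_matrix from [log2_cpm()].
#' @param threshold log2-CPM cut, default 2.
#' @param fraction fraction of samples, default 0.50.
#' @return character vector of kept gene IDs.
#' @export
filter_genes_log2cpm <- function(norm, threshold = 2, fraction = 0.50) {
  n <- ncol(norm$log2cpm)
  keep <- rowSums(norm$log2cpm > threshold) >= ceiling(fraction * n)
  rownames(norm$log2cpm)[keep]
}
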
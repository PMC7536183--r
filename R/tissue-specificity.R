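## TPM normalization, per-tissue replicate averaging, and the Tau and PEM
## tissue-specificity scores. Both scores live on [0, 1] after
## normalization: 0 = broadly expressed, 1 = specific to one tissue.

#' TPM normalization of raw counts
#'
#' Per sample, each gene's count is divided by its length in kilobases and
#' the resulting rates are rescaled to sum to one million, so TPM is
#' comparable across samples of different depth.
#'
#' @param counts expression_matrix of raw counts with gene lengths.
#' @return expression_matrix of TPM values; every non-empty column sums to
#'   1e6.
#' @export
tpm_normalize <- function(counts) {
  len <- counts$gene_meta$length
  if (is.null(len) || anyNA(len)) stop("gene lengths required for TPM")
  if (any(len <= 0)) stop("zero or negative gene length")
  rate <- counts$values / (len / 1000)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero sample(s) left as zero: ",
            paste(colnames(counts$values)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  out <- counts
  out$values <- tpm
  out
}

#' Average expression across replicates by tissue
#'
#' @param em expression_matrix.
#' @return genes x tissues numeric matrix of arithmetic means.
#' @export
tissue_mean <- function(em) {
  tis <- em$sample_meta$tissue
  lv <- unique(tis)
  sums <- t(rowsum(t(em$values), group = factor(tis, levels = lv)))
  n <- as.integer(table(factor(tis, levels = lv)))
  sweep(sums, 2, n, "/")
}

#' Tau tissue-specificity index
#'
#' Tau summarizes in one number whether a gene is expressed in a single
#' tissue (tau = 1) or uniformly across all tissues (tau = 0). With tissue
#' values \eqn{x_i} (optionally log2(x+1)-transformed) and
#' \eqn{\hat x_i = x_i / \max_i x_i},
#' \eqn{\tau = \sum_i (1 - \hat x_i) / (N - 1)}.
#'
#' Genes with zero expression in every tissue cannot be scored and are
#' returned as `NA` (they are excluded from the analysis).
#'
#' @param e genes x tissues matrix of non-negative tissue means.
#' @param log_transform log2(x + 1)-transform tissue values first
#'   (default TRUE).
#' @return named numeric vector of tau values in `[0, 1]` (`NA` for
#'   all-zero genes).
#' @export
tau <- function(e, log_transform = TRUE) {
  e <- as.matrix(e)
  if (ncol(e) < 2) stop("tau needs at least two tissues")
  if (any(e < 0)) stop("negative expression")
  x <- if (log_transform) log2(e + 1) else e
  mx <- apply(x, 1, max)
  out <- rep(NA_real_, nrow(e))
  ok <- mx > 0
  xhat <- x[ok, , drop = FALSE] / mx[ok]
  out[ok] <- rowSums(1 - xhat) / (ncol(e) - 1)
  names(out) <- rownames(e)
  out
}

#' Preferential Expression Measure (PEM)
#'
#' PEM scores a gene's expression in one tissue against the expectation
#' under independence of genes and tissues: with row totals \eqn{r_g},
#' tissue totals \eqn{c_t} and grand total \eqn{G}, the expected value is
#' \eqn{r_g c_t / G} and \eqn{PEM_{gt} = \log_{10}(obs_{gt}/exp_{gt})}.
#' Cells with zero observed expression are reported as `NA` so downstream
#' maxima stay finite. `pem_max_norm` is each gene's maximum PEM across
#' tissues, min-max rescaled to `[0, 1]` across the scored genes.
#'
#' @param e genes x tissues matrix of non-negative tissue means.
#' @return list of class `specificity_result` with `pem` (genes x tissues),
#'   `pem_max` and `pem_max_norm` (per gene; `NA` for all-zero genes).
#' @export
pem <- function(e) {
  e <- as.matrix(e)
  G <- sum(e)
  if (G <= 0) stop("zero grand total")
  r <- rowSums(e); c <- colSums(e)
  expected <- outer(r, c) / G
  p <- log10(e / expected)
  p[e == 0] <- NA_real_
  p[expected == 0] <- NA_real_
  pmax_ <- suppressWarnings(apply(p, 1, max, na.rm = TRUE))
  pmax_[!is.finite(pmax_)] <- NA_real_
  rng <- range(pmax_, na.rm = TRUE)
  norm <- if (diff(rng) > 0) (pmax_ - rng[1]) / diff(rng)
          else ifelse(is.na(pmax_), NA_real_, 0)
  structure(list(pem = p, pem_max = pmax_, pem_max_norm = norm),
            class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("<specificity_result: %d genes x %d tissues>\n",
              nrow(x$pem), ncol(x$pem)))
  invisible(x)
}

#' Tau and PEM scores from a sample-level expression matrix
#'
#' Convenience wrapper: averages replicates by tissue, drops genes with no
#' expression in any tissue, and computes Tau plus per-tissue PEM with the
#' normalized per-gene maximum.
#'
#' @param em expression_matrix (typically TPM).
#' @param log_transform_tau passed to [tau()].
#' @param require_all_tissues strict reading of the exclusion rule: also
#'   drop genes with zero expression in *any* tissue (default FALSE — only
#'   genes unexpressed everywhere are dropped).
#' @return tibble with `gene_id`, `tau`, `pem_max`, `pem_max_norm` and one
#'   `pem_<tissue>` column per tissue; excluded genes are absent.
#' @export
specificity_scores <- function(em, log_transform_tau = TRUE,
                               require_all_tissues = FALSE) {
  e <- tissue_mean(em)
  keep <- if (require_all_tissues) rowSums(e == 0) == 0 else rowSums(e) > 0
  e <- e[keep, , drop = FALSE]
  if (nrow(e) == 0) stop("no genes pass the expression-exclusion rule")
  tv <- tau(e, log_transform = log_transform_tau)
  pv <- pem(e)
  out <- tibble::tibble(gene_id = rownames(e), tau = unname(tv),
                        pem_max = unname(pv$pem_max),
                        pem_max_norm = unname(pv$pem_max_norm))
  pem_cols <- as.data.frame(pv$pem)
  names(pem_cols) <- paste0("pem_", colnames(e))
  dplyr::bind_cols(out, tibble::as_tibble(pem_cols))
}
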
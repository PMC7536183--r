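#' Expression matrix with gene and sample metadata
#'
#' Genes x samples matrix of non-negative values (raw counts or TPM), a
#' sample -> tissue map, and per-gene effective length and biotype.
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs). No negative entries.
#' @param gene_meta tibble with `gene_id`, `biotype`, `length` (bp, > 0);
#'   rows matched to `rownames(values)`.
#' @param sample_meta tibble with `sample`, `tissue`; every column of
#'   `values` must map to exactly one tissue.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_meta, sample_meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (any(values < 0)) stop("negative expression values")
  gene_meta <- tibble::as_tibble(gene_meta)
  sample_meta <- tibble::as_tibble(sample_meta)
  if (!all(rownames(values) %in% gene_meta$gene_id))
    stop("gene_meta missing entries for some genes")
  gene_meta <- gene_meta[match(rownames(values), gene_meta$gene_id), ]
  if (anyDuplicated(sample_meta$sample)) stop("sample mapped to >1 tissue")
  if (!all(colnames(values) %in% sample_meta$sample))
    stop("sample_meta missing entries for some samples")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), ]
  if ("length" %in% names(gene_meta) && any(gene_meta$length <= 0, na.rm = TRUE))
    stop("gene lengths must be positive")
  structure(list(values = values, gene_meta = gene_meta,
                 sample_meta = sample_meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix: %d genes x %d samples, %d tissue(s)>\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_meta$tissue))))
  invisible(x)
}

#' Read / write expression matrices and tissue maps as TSV
#'
#' The matrix TSV has gene IDs in the first column and one column per
#' sample; the tissue map has two columns, `sample` and `tissue`; gene
#' metadata has `gene_id`, `biotype`, `length`.
#'
#' @param matrix_path TSV of the genes x samples matrix.
#' @param genes_path TSV of the gene metadata.
#' @param tissues_path TSV of the sample -> tissue map.
#' @return expression_matrix.
#' @export
read_expression_tsv <- function(matrix_path, genes_path, tissues_path) {
  m <- utils::read.delim(matrix_path, check.names = FALSE)
  vals <- as.matrix(m[, -1, drop = FALSE])
  rownames(vals) <- m[[1]]
  gm <- tibble::as_tibble(utils::read.delim(genes_path))
  sm <- tibble::as_tibble(utils::read.delim(tissues_path))
  expression_matrix(vals, gm, sm)
}

#' @param em expression_matrix.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @rdname read_expression_tsv
#' @return (write) the three paths, invisibly.
#' @export
write_expression_tsv <- function(em, dir, prefix = "expression") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mp <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  gp <- file.path(dir, paste0(prefix, "_genes.tsv"))
  tp <- file.path(dir, paste0(prefix, "_tissues.tsv"))
  tab <- data.frame(gene_id = rownames(em$values), em$values,
                    check.names = FALSE)
  utils::write.table(tab, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(em$gene_meta, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(em$sample_meta, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = mp, genes = gp, tissues = tp))
}
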
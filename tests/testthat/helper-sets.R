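# compact builders for hand-crafted annotation sets

mk_tx <- function(tid, gid, exons, chrom = "chr1", strand = "+",
                  biotype = "lncRNA", source = "t") {
  ex <- do.call(rbind, exons)
  list(
    transcript = tibble::tibble(
      transcript_id = tid, gene_id = gid, chrom = chrom,
      start = min(ex[, 1]), end = max(ex[, 2]), strand = strand,
      biotype = biotype, source = source),
    exons = tibble::tibble(transcript_id = tid, chrom = chrom,
                           start = ex[, 1], end = ex[, 2], strand = strand)
  )
}

mk_gene <- function(gid, start, end, chrom = "chr1", strand = "+",
                    biotype = "lncRNA", sources = "t") {
  tibble::tibble(gene_id = gid, chrom = chrom, start = start, end = end,
                 strand = strand, biotype = biotype, sources = sources)
}

# assemble a set from mk_tx() results; gene records synthesized from
# transcript hulls unless given explicitly
build_set <- function(name, txs, genes = NULL) {
  tr <- dplyr::bind_rows(lapply(txs, `[[`, "transcript"))
  ex <- dplyr::bind_rows(lapply(txs, `[[`, "exons"))
  set <- annotation_set(name, genes = genes %||% empty_genes(),
                        transcripts = tr, exons = ex, validate = FALSE)
  if (is.null(genes)) set <- synthesize_missing_genes(set)
  validate_annotation_set(set)
  set
}

# two-gene reference used by the merge scenario tests
ref_two_genes <- function() {
  r1a <- mk_tx("R1.t1", "R1", list(c(1000, 1500), c(2000, 2500)),
               biotype = "protein_coding", source = "ref")
  r1b <- mk_tx("R1.t2", "R1", list(c(3000, 3500), c(4000, 5000)),
               biotype = "protein_coding", source = "ref")
  r2a <- mk_tx("R2.t1", "R2", list(c(8000, 9000), c(11000, 12000)),
               source = "ref")
  build_set("ref", list(r1a, r1b, r2a),
            genes = dplyr::bind_rows(
              mk_gene("R1", 1000, 5000, biotype = "protein_coding", sources = "ref"),
              mk_gene("R2", 8000, 12000, sources = "ref")))
}
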
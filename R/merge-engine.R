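## Cumulative stepwise intersection of candidate annotations into a
## reference annotation. Reference gene boundaries are never altered:
## candidate genes enclosed in (or identical to) a reference gene donate
## their transcripts; genes straddling a boundary are discarded whole;
## genes sharing no bases with the reference are added as new lncRNA
## entries. Every input record is accounted for in a merge_report.

GENE_FATES <- c("merged_into", "added_new", "discarded_partial")
TX_FATES <- c("added", "duplicate_skipped", "discarded_out_of_bounds",
              "discarded_with_partial_gene")

#' Classify a candidate gene against the reference annotation
#'
#' @param candidate one-row tibble (or list) with `chrom`, `start`, `end`,
#'   `strand`, `gene_id`.
#' @param reference annotation_set.
#' @param strand_aware when TRUE only reference genes on the same strand are
#'   considered (`.` matches only `.`); default FALSE (strand-agnostic),
#'   since antisense transcripts are admitted into gene records.
#' @return list with `class` (one of `"ENCLOSED_OR_FULL"`, `"PARTIAL"`,
#'   `"NONE"`) and `best` (reference gene_id, or `NA` unless enclosed).
#' @export
classify_gene_overlap <- function(candidate, reference, strand_aware = FALSE) {
  cls <- classify_genes_bulk(
    tibble::tibble(gene_id = candidate$gene_id, chrom = candidate$chrom,
                   start = candidate$start, end = candidate$end,
                   strand = candidate$strand),
    reference, strand_aware
  )
  list(class = cls$class[1], best = cls$best[1])
}

# vectorized classification of many candidate genes at once
classify_genes_bulk <- function(cand, reference, strand_aware = FALSE) {
  ref <- reference$genes
  out <- tibble::tibble(gene_id = cand$gene_id,
                        class = rep("NONE", nrow(cand)),
                        best = rep(NA_character_, nrow(cand)))
  if (nrow(ref) == 0 || nrow(cand) == 0) return(out)
  cg <- intervals_granges(cand$chrom, cand$start, cand$end)
  rg <- intervals_granges(ref$chrom, ref$start, ref$end)
  hits <- GenomicRanges::findOverlaps(cg, rg, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (strand_aware) {
    ok <- cand$strand[qi] == ref$strand[si]
    qi <- qi[ok]; si <- si[ok]
  }
  if (!length(qi)) return(out)
  ov_start <- pmax(cand$start[qi], ref$start[si])
  ov_end <- pmin(cand$end[qi], ref$end[si])
  ov_w <- ov_end - ov_start
  enclosed <- ref$start[si] <= cand$start[qi] & cand$end[qi] <= ref$end[si]
  h <- tibble::tibble(q = qi, s = si, w = ov_w, enclosed = enclosed,
                      ref_span = ref$end[si] - ref$start[si],
                      ref_id = ref$gene_id[si])
  # best enclosing gene: largest overlap, then smallest reference span,
  # then lexicographically smallest gene ID
  best <- dplyr::slice_head(
    dplyr::arrange(dplyr::filter(h, .data$enclosed),
                   .data$q, dplyr::desc(.data$w), .data$ref_span, .data$ref_id),
    n = 1, by = "q"
  )
  any_hit <- unique(qi)
  out$class[any_hit] <- "PARTIAL"
  out$class[best$q] <- "ENCLOSED_OR_FULL"
  out$best[best$q] <- best$ref_id
  out
}

#' Admit candidate transcripts into a matched reference gene
#'
#' Transcripts whose span falls outside the reference gene boundary are
#' discarded (mis-assigned records); transcripts whose exon chain equals an
#' existing transcript of the gene are skipped as duplicates; the rest are
#' added with all their exons and provenance. The gene boundary is never
#' changed; admitted non-coding transcripts keep their own biotype.
#'
#' @param set annotation_set containing the reference gene.
#' @param gene_id reference gene to receive the transcripts.
#' @param candidate annotation_set holding the candidate transcripts.
#' @param transcript_ids candidate transcript IDs to admit.
#' @return list with the updated `set` and `fates` (tibble transcript_id,
#'   fate).
#' @export
admit_transcripts <- function(set, gene_id, candidate, transcript_ids) {
  g <- set$genes[set$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) stop("unknown reference gene: ", gene_id)
  tr <- candidate$transcripts[match(transcript_ids, candidate$transcripts$transcript_id), ]
  if (any(tr$chrom != g$chrom)) stop("chromosome mismatch admitting into ", gene_id)
  oob <- tr$start < g$start | tr$end > g$end
  exist_keys <- transcript_chain_keys(
    subset_transcripts(set, set$transcripts$transcript_id[set$transcripts$gene_id == gene_id]))
  cand_keys <- transcript_chain_keys(subset_transcripts(candidate, tr$transcript_id))
  key <- unname(cand_keys[tr$transcript_id])
  dup <- !oob & (key %in% exist_keys | duplicated(ifelse(oob, NA, key), incomparables = NA))
  fate <- ifelse(oob, "discarded_out_of_bounds",
                 ifelse(dup, "duplicate_skipped", "added"))
  add_ids <- tr$transcript_id[fate == "added"]
  if (length(add_ids)) {
    new_tr <- tr[fate == "added", ]
    new_tr$gene_id <- gene_id
    # resolve transcript-ID collisions with the accumulating set
    clash <- new_tr$transcript_id %in% set$transcripts$transcript_id
    new_ids <- ifelse(clash, paste0(new_tr$transcript_id, "_", new_tr$source),
                      new_tr$transcript_id)
    new_ex <- candidate$exons[candidate$exons$transcript_id %in% add_ids, ]
    new_ex$transcript_id <- new_ids[match(new_ex$transcript_id, new_tr$transcript_id)]
    new_tr$transcript_id <- new_ids
    set$transcripts <- dplyr::bind_rows(set$transcripts, new_tr)
    set$exons <- dplyr::bind_rows(set$exons, new_ex)
    i <- which(set$genes$gene_id == gene_id)
    set$genes$sources[i] <- join_sources(
      split_sources(paste(c(set$genes$sources[i], new_tr$source), collapse = ",")))
  }
  list(set = set, fates = tibble::tibble(transcript_id = tr$transcript_id, fate = fate))
}

subset_transcripts <- function(set, transcript_ids) {
  annotation_set(
    set$name,
    genes = set$genes[0, ],
    transcripts = set$transcripts[set$transcripts$transcript_id %in% transcript_ids, ],
    exons = set$exons[set$exons$transcript_id %in% transcript_ids, ],
    validate = FALSE
  )
}

#' Merge one candidate annotation into the reference
#'
#' One step of the cumulative stepwise intersection. Every candidate gene is
#' classified against the (input) reference: enclosed or fully overlapping
#' genes donate their transcripts into the best reference gene; partially
#' overlapping genes are discarded whole, so reference gene boundaries are
#' never re-defined; non-overlapping genes are added as new lncRNA entries
#' with all transcripts and exons.
#'
#' @param reference normalized annotation_set.
#' @param candidate normalized annotation_set.
#' @param strand_aware passed to [classify_gene_overlap()].
#' @return list with `set` (merged annotation_set) and `report`
#'   (merge_report).
#' @export
merge_pair <- function(reference, candidate, strand_aware = FALSE) {
  cls <- classify_genes_bulk(candidate$genes, reference, strand_aware)
  out <- reference
  gene_fates <- tibble::tibble(gene_id = cls$gene_id,
                               fate = character(nrow(cls)),
                               target = NA_character_)
  tx_fates_list <- list()
  renamed <- character(0)

  for (i in seq_len(nrow(cls))) {
    gid <- cls$gene_id[i]
    tx_ids <- candidate$transcripts$transcript_id[candidate$transcripts$gene_id == gid]
    if (cls$class[i] == "PARTIAL") {
      gene_fates$fate[i] <- "discarded_partial"
      tx_fates_list[[i]] <- tibble::tibble(
        transcript_id = tx_ids, gene_id = gid,
        fate = "discarded_with_partial_gene")
    } else if (cls$class[i] == "ENCLOSED_OR_FULL") {
      gene_fates$fate[i] <- "merged_into"
      gene_fates$target[i] <- cls$best[i]
      adm <- admit_transcripts(out, cls$best[i], candidate, tx_ids)
      out <- adm$set
      tx_fates_list[[i]] <- tibble::tibble(
        transcript_id = adm$fates$transcript_id, gene_id = gid,
        fate = adm$fates$fate)
    } else {
      gene_fates$fate[i] <- "added_new"
      g <- candidate$genes[candidate$genes$gene_id == gid, ]
      new_gid <- gid
      if (new_gid %in% out$genes$gene_id) {
        new_gid <- paste0(gid, "_", candidate$name)
        renamed <- c(renamed, gid)
      }
      g$gene_id <- new_gid
      g$biotype <- "lncRNA"   # non-overlapping genes enter as lncRNA entries
      tr <- candidate$transcripts[candidate$transcripts$gene_id == gid, ]
      tr$gene_id <- new_gid
      clash <- tr$transcript_id %in% out$transcripts$transcript_id
      new_tids <- ifelse(clash, paste0(tr$transcript_id, "_", candidate$name),
                         tr$transcript_id)
      ex <- candidate$exons[candidate$exons$transcript_id %in% tx_ids, ]
      ex$transcript_id <- new_tids[match(ex$transcript_id, tr$transcript_id)]
      tr$transcript_id <- new_tids
      out$genes <- dplyr::bind_rows(out$genes, g)
      out$transcripts <- dplyr::bind_rows(out$transcripts, tr)
      out$exons <- dplyr::bind_rows(out$exons, ex)
      gene_fates$target[i] <- new_gid
      tx_fates_list[[i]] <- tibble::tibble(transcript_id = tx_ids,
                                           gene_id = gid, fate = "added")
    }
  }
  tx_fates <- dplyr::bind_rows(tx_fates_list)
  if (nrow(tx_fates) == 0) {
    tx_fates <- tibble::tibble(transcript_id = character(),
                               gene_id = character(), fate = character())
  }
  report <- structure(
    list(step = candidate$name,
         gene_fates = gene_fates,
         transcript_fates = tx_fates,
         renamed_genes = renamed,
         counts = list(
           genes = table(factor(gene_fates$fate, levels = GENE_FATES)),
           transcripts = table(factor(tx_fates$fate, levels = TX_FATES)))),
    class = "merge_report")
  validate_annotation_set(out)
  list(set = out, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf("<merge_report step '%s'>\n", x$step))
  cat("  genes:       ", paste(names(x$counts$genes), as.integer(x$counts$genes),
                               sep = "=", collapse = "  "), "\n")
  cat("  transcripts: ", paste(names(x$counts$transcripts),
                               as.integer(x$counts$transcripts),
                               sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Cumulative stepwise merge of an ordered list of candidate annotations
#'
#' Left fold of [merge_pair()]: the merged output of step *k* is the
#' reference of step *k + 1*, so the order of the candidate list matters.
#'
#' @param reference normalized annotation_set.
#' @param candidates ordered list of normalized annotation_sets.
#' @param strand_aware passed through to each step.
#' @return list with `set` (final merged annotation_set) and `reports`
#'   (list of merge_report, in order).
#' @export
merge_all <- function(reference, candidates, strand_aware = FALSE) {
  reports <- vector("list", length(candidates))
  out <- reference
  for (k in seq_along(candidates)) {
    step <- merge_pair(out, candidates[[k]], strand_aware)
    out <- step$set
    reports[[k]] <- step$report
  }
  names(reports) <- vapply(candidates, function(s) s$name, character(1))
  list(set = out, reports = reports)
}

#' Per-gene source membership and upset-style intersection counts
#'
#' Gene membership is the union of its transcripts' source tags; counts are
#' reported for every non-empty source combination observed.
#'
#' @param merged annotation_set with provenance.
#' @return list with `membership` (tibble gene_id, sources) and
#'   `intersections` (tibble combination, n_sources, count; counts sum to
#'   the number of genes).
#' @export
contribution_matrix <- function(merged) {
  merged <- refresh_gene_sources(merged)
  mem <- tibble::tibble(gene_id = merged$genes$gene_id,
                        sources = merged$genes$sources)
  counts <- dplyr::count(mem, .data$sources, name = "count")
  counts$n_sources <- lengths(split_sources(counts$sources))
  counts <- counts[order(-counts$n_sources, counts$sources), ]
  names(counts)[names(counts) == "sources"] <- "combination"
  list(membership = mem,
       intersections = tibble::as_tibble(counts[, c("combination", "n_sources", "count")]))
}

#' Write a merge report as TSV
#'
#' One row per input record (genes then transcripts) with its fate.
#'
#' @param report merge_report.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_merge_report <- function(report, path) {
  g <- report$gene_fates
  g$record <- "gene"; g$transcript_id <- NA_character_
  t <- report$transcript_fates
  t$record <- "transcript"; t$target <- NA_character_
  tab <- dplyr::bind_rows(
    g[, c("record", "gene_id", "transcript_id", "fate", "target")],
    t[, c("record", "gene_id", "transcript_id", "fate", "target")])
  tab <- cbind(step = report$step, tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
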
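## GFF3/GTF input and output.
## Internal coordinates are 0-based half-open; files are 1-based inclusive.
## Parsing is tokenized by rtracklayer; hierarchy resolution, dialect
## sniffing and line-level validation happen here.

#' Parse a GFF3/GTF annotation into an annotation_set
#'
#' Reads gene, transcript (or mRNA) and exon records, resolves the
#' gene -> transcript -> exon hierarchy via `ID`/`Parent` (GFF3) or
#' `gene_id`/`transcript_id` (GTF) attributes, and converts file coordinates
#' (1-based inclusive) to internal 0-based half-open. Feature types other
#' than gene/transcript/exon (CDS, UTRs, ...) are ignored. Transcripts whose
#' `gene_id` has no gene record are kept as orphans and can be resolved with
#' [synthesize_missing_genes()]. Transcript spans are normalized to the hull
#' of their exons; gene spans are taken from the gene record as written.
#'
#' @param path path to a GFF3 or GTF file.
#' @param dialect `"auto"` (default; sniffed from the attribute syntax),
#'   `"gff3"` or `"gtf"`.
#' @param source_tag source label applied to every record. When `NULL`, the
#'   provenance already in the file is used: a `sources` attribute if
#'   present, otherwise column 2.
#' @param name name for the returned set (defaults to `source_tag` or the
#'   file base name).
#' @return annotation_set.
#' @export
parse_annotation <- function(path, dialect = c("auto", "gff3", "gtf"),
                             source_tag = NULL, name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^\\s*(#|$)", lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1]]
    stop("unparseable line ", bad, " in ", path,
         ": expected 9 tab-separated fields, found ", nfield[which(nfield != 9L)[1]])
  }
  if (dialect == "auto") dialect <- sniff_dialect(lines[body])
  if (!any(body)) {
    nm <- name %||% source_tag %||% basename(path)
    return(annotation_set(nm))
  }

  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  keep <- type %in% c("gene", "transcript", "mRNA", "exon")
  gr <- gr[keep]; mc <- mc[keep, , drop = FALSE]; type <- type[keep]
  type[type == "mRNA"] <- "transcript"

  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  col2 <- as.character(mc$source)

  attr_chr <- function(key) {
    if (!key %in% colnames(mc)) return(rep(NA_character_, length(gr)))
    v <- mc[[key]]
    if (methods::is(v, "List")) {
      vapply(v, function(e) if (length(e)) as.character(e[1]) else NA_character_,
             character(1))
    } else as.character(v)
  }
  id <- attr_chr("ID")
  parent <- attr_chr("Parent")
  gene_id_attr <- attr_chr("gene_id")
  tx_id_attr <- attr_chr("transcript_id")

  biotype <- dplyr::coalesce(attr_chr("biotype"),
                             attr_chr("gene_biotype"), attr_chr("gene_type"),
                             attr_chr("transcript_biotype"), attr_chr("transcript_type"))
  biotype <- normalize_biotype(biotype)
  sources_attr <- attr_chr("sources")
  src <- if (is.null(source_tag)) dplyr::coalesce(sources_attr, col2)
         else rep(as.character(source_tag), length(gr))

  is_g <- type == "gene"; is_t <- type == "transcript"; is_e <- type == "exon"

  gene_ids <- dplyr::coalesce(id[is_g], gene_id_attr[is_g])
  if (anyNA(gene_ids)) stop("gene record without ID/gene_id in ", path)
  genes <- tibble::tibble(
    gene_id = gene_ids, chrom = chrom[is_g], start = start0[is_g],
    end = end0[is_g], strand = strand[is_g], biotype = biotype[is_g],
    sources = join_sources(split_sources(src[is_g]))
  )

  tx_ids <- dplyr::coalesce(id[is_t], tx_id_attr[is_t])
  if (anyNA(tx_ids)) stop("transcript record without ID/transcript_id in ", path)
  tx_gene <- dplyr::coalesce(parent[is_t], gene_id_attr[is_t])
  if (anyNA(tx_gene)) {
    stop("transcript '", tx_ids[which(is.na(tx_gene))[1]],
         "' has no Parent/gene_id attribute in ", path)
  }
  transcripts <- tibble::tibble(
    transcript_id = tx_ids, gene_id = tx_gene, chrom = chrom[is_t],
    start = start0[is_t], end = end0[is_t], strand = strand[is_t],
    biotype = biotype[is_t], source = src[is_t]
  )

  ex_tx <- dplyr::coalesce(parent[is_e], tx_id_attr[is_e])
  if (anyNA(ex_tx)) {
    stop("exon with no resolvable transcript parent and no transcript_id in ",
         path)
  }
  exons <- tibble::tibble(
    transcript_id = ex_tx, chrom = chrom[is_e], start = start0[is_e],
    end = end0[is_e], strand = strand[is_e]
  )
  unknown <- setdiff(exons$transcript_id, transcripts$transcript_id)
  if (length(unknown)) {
    stop("exon references transcript '", unknown[1],
         "' with no transcript record in ", path)
  }

  res <- normalize_exon_chains(transcripts, exons)
  nm <- name %||% source_tag %||% basename(path)
  annotation_set(nm, genes = genes, transcripts = res$transcripts,
                 exons = res$exons)
}

sniff_dialect <- function(body_lines) {
  if (!length(body_lines)) return("gff3")
  attrs <- vapply(strsplit(utils::head(body_lines, 50), "\t", fixed = TRUE),
                  function(f) f[9], character(1))
  if (any(grepl("(^|;)\\s*(ID|Parent)=", attrs))) return("gff3")
  if (any(grepl("\\w+\\s+\"[^\"]*\"", attrs))) return("gtf")
  if (any(grepl("=", attrs, fixed = TRUE))) "gff3" else "gtf"
}

normalize_biotype <- function(x) {
  out <- rep("other", length(x))
  out[!is.na(x) & x == "protein_coding"] <- "protein_coding"
  lnc <- !is.na(x) & grepl("lnc|linc|antisense|non_?coding", x, ignore.case = TRUE)
  out[lnc & out != "protein_coding"] <- "lncRNA"
  out
}

# sort exons within transcripts and union any overlapping pairs so chains are
# non-nested; transcript spans become the hull of their exons
normalize_exon_chains <- function(transcripts, exons) {
  if (nrow(exons)) {
    gr <- GenomicRanges::GRanges(exons$transcript_id,
                                 IRanges::IRanges(exons$start + 1L, exons$end))
    red <- GenomicRanges::reduce(gr)   # per-transcript: seqnames = transcript_id
    tx <- as.character(GenomicRanges::seqnames(red))
    meta <- transcripts[match(tx, transcripts$transcript_id), ]
    exons <- tibble::tibble(
      transcript_id = tx, chrom = meta$chrom,
      start = GenomicRanges::start(red) - 1L, end = GenomicRanges::end(red),
      strand = meta$strand
    )
    exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                         exons$start), ]
    hull <- dplyr::summarise(dplyr::group_by(exons, .data$transcript_id),
                             start = min(.data$start), end = max(.data$end),
                             .groups = "drop")
    m <- match(transcripts$transcript_id, hull$transcript_id)
    hit <- !is.na(m)
    transcripts$start[hit] <- hull$start[m[hit]]
    transcripts$end[hit] <- hull$end[m[hit]]
  }
  list(transcripts = transcripts, exons = exons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create gene records for orphan transcripts
#'
#' Some source annotations carry transcript/exon records with no gene line.
#' For every such `gene_id` a gene record is synthesized spanning from the
#' first exon start to the last exon end over all of its transcripts, with
#' the transcript strand as the gene strand. Existing genes are untouched.
#'
#' @param set annotation_set (may contain orphan transcripts).
#' @return annotation_set with a gene record for every transcript.
#' @export
synthesize_missing_genes <- function(set) {
  orphans <- setdiff(set$transcripts$gene_id, set$genes$gene_id)
  if (!length(orphans)) return(set)
  tr <- set$transcripts[set$transcripts$gene_id %in% orphans, ]
  new_genes <- dplyr::summarise(
    dplyr::group_by(tr, .data$gene_id),
    n_chrom = dplyr::n_distinct(.data$chrom),
    chrom = .data$chrom[1],
    start = min(.data$start), end = max(.data$end),
    strand = if (dplyr::n_distinct(.data$strand) == 1L) .data$strand[1] else ".",
    biotype = pick_biotype(.data$biotype),
    sources = paste(sort(unique(unlist(split_sources(.data$source)))),
                    collapse = ","),
    .groups = "drop"
  )
  if (any(new_genes$n_chrom > 1L)) {
    stop("orphan transcripts under gene '",
         new_genes$gene_id[new_genes$n_chrom > 1L][1],
         "' lie on conflicting chromosomes")
  }
  if (any(new_genes$strand == ".")) {
    warning("conflicting transcript strands for synthesized gene(s): ",
            paste(new_genes$gene_id[new_genes$strand == "."], collapse = ", "),
            "; gene strand set to '.'")
  }
  set$genes <- dplyr::bind_rows(
    set$genes,
    new_genes[, c("gene_id", "chrom", "start", "end", "strand", "biotype", "sources")]
  )
  validate_annotation_set(set)
  set
}

pick_biotype <- function(b) {
  if ("protein_coding" %in% b) "protein_coding"
  else if ("lncRNA" %in% b) "lncRNA"
  else "other"
}

#' Remove redundant transcript records
#'
#' Transcripts with the identical (chrom, strand, ordered exon coordinate
#' chain) collapse to one record; the first-seen transcript ID is kept.
#' Genes whose transcripts were all collapsed away are removed too.
#'
#' @param set annotation_set.
#' @return list with `set` (deduplicated annotation_set), `removed` (total
#'   removed records), `removed_transcripts`, `removed_genes`.
#' @export
deduplicate <- function(set) {
  keys <- transcript_chain_keys(set)
  tr <- set$transcripts
  chain <- unname(keys[tr$transcript_id])
  dup <- duplicated(chain)
  drop_tx <- tr$transcript_id[dup]
  had_tx <- unique(tr$gene_id)
  tr2 <- tr[!dup, ]
  drop_genes <- setdiff(had_tx, tr2$gene_id)
  set$transcripts <- tr2
  set$exons <- set$exons[set$exons$transcript_id %in% tr2$transcript_id, ]
  set$genes <- set$genes[!set$genes$gene_id %in% drop_genes, ]
  set <- refresh_gene_sources(set)
  list(set = set,
       removed = length(drop_tx) + length(drop_genes),
       removed_transcripts = length(drop_tx),
       removed_genes = length(drop_genes))
}

#' Normalize an annotation set for merging
#'
#' Synthesizes genes for orphan transcripts, then removes redundant
#' records — the two preparation steps every source goes through before
#' entering the stepwise merge.
#'
#' @param set annotation_set.
#' @return normalized annotation_set.
#' @export
normalize_annotation <- function(set) {
  deduplicate(synthesize_missing_genes(set))$set
}

#' Write an annotation set as GFF3 or GTF
#'
#' Records are emitted 1-based inclusive, genes sorted by chromosome then
#' start, transcripts nested under genes and exons under transcripts.
#' Attributes carry `gene_id`/`transcript_id` (GTF) or `ID`/`Parent` (GFF3)
#' plus `biotype` and `sources`, so that parsing the file back reproduces
#' the set.
#'
#' @param set annotation_set.
#' @param path output path.
#' @param dialect `"gff3"` or `"gtf"`.
#' @return `path`, invisibly.
#' @export
write_gff <- function(set, path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  g <- set$genes[order(set$genes$chrom, set$genes$start, set$genes$gene_id), ]
  tr <- set$transcripts
  ex <- set$exons
  lines <- if (dialect == "gff3") "##gff-version 3" else "#!format gtf"
  esc <- function(x) x  # identifiers in this pipeline are plain tokens
  fmt <- function(chrom, src, type, start, end, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, src, type,
            start + 1L, end, strand, attrs)
  }
  out <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    first_src <- split_sources(gi$sources)[[1]][1]
    gattr <- if (dialect == "gff3") {
      sprintf("ID=%s;biotype=%s;sources=%s", gi$gene_id, gi$biotype, gi$sources)
    } else {
      sprintf("gene_id \"%s\"; biotype \"%s\"; sources \"%s\";",
              gi$gene_id, gi$biotype, gi$sources)
    }
    gl <- fmt(gi$chrom, first_src, "gene", gi$start, gi$end, gi$strand, gattr)
    ti <- tr[tr$gene_id == gi$gene_id, ]
    ti <- ti[order(ti$start, ti$transcript_id), ]
    tl <- character(0)
    for (j in seq_len(nrow(ti))) {
      tj <- ti[j, ]
      tattr <- if (dialect == "gff3") {
        sprintf("ID=%s;Parent=%s;biotype=%s;sources=%s",
                tj$transcript_id, tj$gene_id, tj$biotype, tj$source)
      } else {
        sprintf("gene_id \"%s\"; transcript_id \"%s\"; biotype \"%s\"; sources \"%s\";",
                tj$gene_id, tj$transcript_id, tj$biotype, tj$source)
      }
      ej <- ex[ex$transcript_id == tj$transcript_id, ]
      ej <- ej[order(ej$start), ]
      eattr <- if (dialect == "gff3") {
        sprintf("Parent=%s", tj$transcript_id)
      } else {
        sprintf("gene_id \"%s\"; transcript_id \"%s\";",
                tj$gene_id, tj$transcript_id)
      }
      el <- fmt(ej$chrom, tj$source, "exon", ej$start, ej$end, ej$strand, eattr)
      tl <- c(tl, fmt(tj$chrom, tj$source, "transcript", tj$start, tj$end,
                      tj$strand, tattr), el)
    }
    out[[i]] <- c(gl, tl)
  }
  con <- file(path, open = "wb")  # LF endings for byte-stable output
  on.exit(close(con))
  writeLines(c(lines, unlist(out)), con = con, sep = "\n")
  invisible(path)
}

#' Flat TSV dump of transcript records
#'
#' One row per transcript with its gene context, exon chain and provenance —
#' the downloadable text-table view of an annotation set.
#'
#' @param set annotation_set.
#' @param path output path.
#' @param sep field separator (tab by default; `","` for CSV).
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(set, path, sep = "\t") {
  ex <- set$exons[order(set$exons$transcript_id, set$exons$start), ]
  chains <- dplyr::summarise(
    dplyr::group_by(ex, .data$transcript_id),
    n_exons = dplyr::n(),
    exon_starts = paste(.data$start, collapse = ","),
    exon_ends = paste(.data$end, collapse = ","),
    .groups = "drop"
  )
  tab <- dplyr::left_join(set$transcripts, chains, by = "transcript_id")
  g <- set$genes[, c("gene_id", "start", "end", "biotype", "sources")]
  names(g) <- c("gene_id", "gene_start", "gene_end", "gene_biotype", "gene_sources")
  tab <- dplyr::left_join(tab, g, by = "gene_id")
  tab <- tab[order(tab$chrom, tab$gene_start, tab$gene_id, tab$start), ]
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
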
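#' Hierarchical annotation container
#'
#' An `annotation_set` holds a gene -> transcript -> exon catalogue in three
#' flat tables, with per-record source provenance. All coordinates are
#' internal 0-based half-open; GFF/GTF I/O converts to and from the 1-based
#' inclusive file convention.
#'
#' @param name source tag for the set (e.g. the annotation database name).
#' @param genes tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`, `sources` (comma-joined, sorted source tags).
#' @param transcripts tibble with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `biotype`, `source`.
#' @param exons tibble with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param validate run structural checks (default TRUE).
#'
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(name, genes = empty_genes(), transcripts = empty_transcripts(),
                           exons = empty_exons(), validate = TRUE) {
  x <- structure(
    list(
      name = as.character(name),
      genes = tibble::as_tibble(genes),
      transcripts = tibble::as_tibble(transcripts),
      exons = tibble::as_tibble(exons)
    ),
    class = "annotation_set"
  )
  if (validate) validate_annotation_set(x)
  x
}

#' @rdname annotation_set
#' @export
empty_genes <- function() {
  tibble::tibble(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), biotype = character(),
    sources = character()
  )
}

#' @rdname annotation_set
#' @export
empty_transcripts <- function() {
  tibble::tibble(
    transcript_id = character(), gene_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    biotype = character(), source = character()
  )
}

#' @rdname annotation_set
#' @export
empty_exons <- function() {
  tibble::tibble(
    transcript_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character()
  )
}

#' Structural validation of an annotation set
#'
#' Checks interval sanity (start < end), unique gene IDs, transcript/exon
#' linkage, and chrom/strand agreement between exons and their transcript.
#' Transcripts whose `gene_id` has no gene record are permitted (orphans,
#' resolved later by [synthesize_missing_genes()]).
#'
#' @param x annotation_set.
#' @return `x`, invisibly; errors describe the first violation found.
#' @export
validate_annotation_set <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  g <- x$genes; tr <- x$transcripts; ex <- x$exons
  if (anyDuplicated(g$gene_id)) {
    stop("duplicated gene_id in set '", x$name, "': ",
         paste(unique(g$gene_id[duplicated(g$gene_id)]), collapse = ", "))
  }
  if (anyDuplicated(tr$transcript_id)) {
    stop("duplicated transcript_id in set '", x$name, "'")
  }
  if (any(g$start >= g$end)) stop("gene with start >= end")
  if (any(tr$start >= tr$end)) stop("transcript with start >= end")
  if (any(ex$start >= ex$end)) stop("exon with start >= end")
  bad <- setdiff(ex$transcript_id, tr$transcript_id)
  if (length(bad)) stop("exon(s) reference unknown transcript: ", bad[1])
  if (nrow(tr) > 0) {
    n_ex <- table(ex$transcript_id)
    none <- setdiff(tr$transcript_id, names(n_ex))
    if (length(none)) stop("transcript without exons: ", none[1])
  }
  # exon chrom/strand must agree with parent transcript
  if (nrow(ex) > 0) {
    key <- stats::setNames(paste(tr$chrom, tr$strand), tr$transcript_id)
    mism <- paste(ex$chrom, ex$strand) != unname(key[ex$transcript_id])
    if (any(mism)) stop("exon chrom/strand disagrees with transcript: ",
                        ex$transcript_id[which(mism)[1]])
  }
  invisible(x)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set '%s': %d genes, %d transcripts, %d exons on %d chromosome(s)>\n",
              x$name, nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Record counts of an annotation set
#'
#' @param x annotation_set.
#' @return named integer vector with `genes`, `transcripts`, `exons`.
#' @export
annotation_counts <- function(x) {
  c(genes = nrow(x$genes), transcripts = nrow(x$transcripts), exons = nrow(x$exons))
}

## ---- source-tag helpers -------------------------------------------------

join_sources <- function(tags) {
  vapply(tags, function(t) paste(sort(unique(t)), collapse = ","), character(1))
}

split_sources <- function(s) strsplit(s, ",", fixed = TRUE)

add_source <- function(joined, tag) {
  join_sources(lapply(split_sources(joined), function(t) c(t, tag)))
}

## ---- exon-chain identity ------------------------------------------------

#' Exon-chain keys for transcript identity
#'
#' Transcript identity for redundancy removal is the exact ordered exon
#' coordinate chain on the same chromosome and strand.
#'
#' @param set annotation_set.
#' @return named character vector, one key per transcript_id.
#' @export
transcript_chain_keys <- function(set) {
  ex <- set$exons
  if (nrow(ex) == 0) return(stats::setNames(character(), character()))
  o <- order(ex$transcript_id, ex$start, ex$end)
  pieces <- split(paste(ex$start[o], ex$end[o], sep = "-"), ex$transcript_id[o])
  first <- !duplicated(ex$transcript_id[o])
  head_of <- stats::setNames(paste0(ex$chrom[o][first], ":", ex$strand[o][first], ":"),
                             ex$transcript_id[o][first])
  chains <- vapply(pieces, paste, character(1), collapse = ",")
  stats::setNames(paste0(head_of[names(chains)], chains), names(chains))
}

## ---- GRanges bridge -----------------------------------------------------

# internal 0-based half-open -> GRanges (1-based inclusive)
genes_granges <- function(set, use_strand = FALSE) {
  g <- set$genes
  GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = if (use_strand) ifelse(g$strand %in% c("+", "-"), g$strand, "*") else "*",
    gene_id = g$gene_id
  )
}

intervals_granges <- function(chrom, start, end, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = if (is.null(strand)) "*" else ifelse(strand %in% c("+", "-"), strand, "*")
  )
}

#' Recompute per-gene source sets from transcript provenance
#' @param set annotation_set.
#' @return annotation_set with `genes$sources` = union of transcript sources
#'   (genes without transcripts keep their recorded sources).
#' @export
refresh_gene_sources <- function(set) {
  if (nrow(set$transcripts) == 0) return(set)
  agg <- dplyr::summarise(
    dplyr::group_by(set$transcripts, .data$gene_id),
    src = paste(sort(unique(unlist(split_sources(.data$source)))), collapse = ","),
    .groups = "drop"
  )
  m <- match(set$genes$gene_id, agg$gene_id)
  hit <- !is.na(m)
  set$genes$sources[hit] <- agg$src[m[hit]]
  set
}
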
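## Rule-based positional classification of lncRNA transcripts relative to
## reference mRNA transcripts. Genic pairs (span overlap) are labelled
## sense/antisense x exonic/intronic x overlapping/containing/nested;
## intergenic pairs within the search window are labelled
## upstream/downstream x divergent/convergent/same_strand with a bp
## distance. Pre-filters drop transcripts under 200 bp of exonic sequence
## and transcripts mostly covered (in sense) by protein-coding exons.

#' Classifier configuration
#'
#' @param window_min initial intergenic search radius in bp (default
#'   10,000); expanded up to `window_max` until a partner is found.
#' @param window_max maximum intergenic search radius in bp (default
#'   100,000).
#' @param min_size minimum summed exon length in bp (default 200).
#' @param sense_overlap_fraction fraction of a candidate's exonic length
#'   covered in sense by reference protein-coding exons above which the
#'   candidate is excluded (default 0.75, strict `>`).
#' @param strict_band when TRUE, intergenic partners closer than
#'   `window_min` are not reported (alternative reading of the window).
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(window_min = 10000L, window_max = 100000L,
                              min_size = 200L, sense_overlap_fraction = 0.75,
                              strict_band = FALSE) {
  stopifnot(window_min <= window_max, min_size >= 0,
            sense_overlap_fraction > 0, sense_overlap_fraction <= 1)
  structure(list(window_min = as.integer(window_min),
                 window_max = as.integer(window_max),
                 min_size = as.integer(min_size),
                 sense_overlap_fraction = sense_overlap_fraction,
                 strict_band = isTRUE(strict_band)),
            class = "classifier_config")
}

tx_exons <- function(set, transcript_ids) {
  set$exons[set$exons$transcript_id %in% transcript_ids, , drop = FALSE]
}

exonic_length <- function(set, transcript_ids) {
  ex <- tx_exons(set, transcript_ids)
  if (nrow(ex) == 0) return(stats::setNames(numeric(0), character(0)))
  agg <- rowsum(ex$end - ex$start, ex$transcript_id)
  stats::setNames(agg[, 1], rownames(agg))
}

#' Pre-filter candidate lncRNA transcripts
#'
#' Removes transcripts with under `min_size` bp of summed exon length
#' (monoexonic transcripts are retained as long as they meet the length
#' rule) and transcripts whose same-strand exonic overlap with reference
#' protein-coding exons exceeds `sense_overlap_fraction` of their own
#' exonic length. Antisense overlap never excludes.
#'
#' @param candidates annotation_set of candidate lncRNA transcripts.
#' @param reference annotation_set with protein-coding transcripts.
#' @param cfg classifier_config.
#' @return list with `kept`, `removed_short`, `removed_sense_overlap`
#'   (character vectors of transcript IDs).
#' @export
prefilter <- function(candidates, reference, cfg = classifier_config()) {
  ids <- candidates$transcripts$transcript_id
  elen <- exonic_length(candidates, ids)[ids]
  short <- ids[elen < cfg$min_size]
  rest <- setdiff(ids, short)

  pc_tx <- reference$transcripts[reference$transcripts$biotype == "protein_coding", ]
  pc_ex <- tx_exons(reference, pc_tx$transcript_id)
  frac <- stats::setNames(rep(0, length(rest)), rest)
  if (nrow(pc_ex) > 0 && length(rest) > 0) {
    cand_ex <- tx_exons(candidates, rest)
    cg <- GenomicRanges::GRanges(cand_ex$chrom,
                                 IRanges::IRanges(cand_ex$start + 1L, cand_ex$end),
                                 strand = ifelse(cand_ex$strand %in% c("+", "-"),
                                                 cand_ex$strand, "*"))
    # per strand+chrom union of protein-coding exon space
    pg <- GenomicRanges::reduce(GenomicRanges::GRanges(
      pc_ex$chrom, IRanges::IRanges(pc_ex$start + 1L, pc_ex$end),
      strand = ifelse(pc_ex$strand %in% c("+", "-"), pc_ex$strand, "*")))
    hits <- GenomicRanges::findOverlaps(cg, pg, ignore.strand = FALSE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (length(qi)) {
      w <- pmin(GenomicRanges::end(cg)[qi], GenomicRanges::end(pg)[si]) -
        pmax(GenomicRanges::start(cg)[qi], GenomicRanges::start(pg)[si]) + 1L
      ov <- rowsum(as.numeric(w), cand_ex$transcript_id[qi])
      frac[rownames(ov)] <- ov[, 1] / elen[rownames(ov)]
    }
  }
  sense_out <- rest[frac[rest] > cfg$sense_overlap_fraction]
  list(kept = setdiff(rest, sense_out),
       removed_short = short,
       removed_sense_overlap = sense_out)
}

#' Classify a genic lncRNA / partner transcript pair
#'
#' Requires the two spans to share at least one base. Direction is sense
#' when strands are equal, antisense otherwise; location is exonic when any
#' lncRNA exon shares a base with any partner exon, else intronic; the
#' subtype is nested (lncRNA inside the partner span, ties included),
#' containing (partner inside the lncRNA) or overlapping.
#'
#' @param lnc,partner one-row transcript tibbles with `transcript_id`,
#'   `chrom`, `start`, `end`, `strand`.
#' @param lnc_exons,partner_exons exon tibbles (`start`, `end`).
#' @return one-row tibble (a classification record).
#' @export
classify_genic <- function(lnc, partner, lnc_exons, partner_exons) {
  if (lnc$chrom != partner$chrom) stop("different chromosomes")
  if (lnc$end <= partner$start || partner$end <= lnc$start)
    stop("spans do not overlap; use classify_intergenic")
  direction <- if (lnc$strand == partner$strand) "sense" else "antisense"
  exonic <- any(outer(lnc_exons$start, partner_exons$end, "<") &
                  outer(lnc_exons$end, partner_exons$start, ">"))
  location <- if (exonic) "exonic" else "intronic"
  subtype <- if (lnc$start >= partner$start && lnc$end <= partner$end) "nested"
  else if (partner$start >= lnc$start && partner$end <= lnc$end) "containing"
  else "overlapping"
  tibble::tibble(
    lnc_transcript_id = lnc$transcript_id,
    partner_transcript_id = partner$transcript_id,
    type = "GENIC", direction = direction, location = location,
    subtype = subtype, distance = NA_integer_
  )
}

#' Classify an intergenic lncRNA / partner transcript pair
#'
#' Distance is the bp gap between the nearest span boundaries. The side
#' (upstream/downstream) is the partner's position relative to the lncRNA's
#' 5' end; the orientation is same_strand when strands are equal, otherwise
#' divergent when the 5' ends face each other (head-to-head) and convergent
#' when the 3' ends face each other (tail-to-tail).
#'
#' @param lnc,partner one-row transcript tibbles.
#' @param cfg classifier_config (used for the window invariant only).
#' @return one-row tibble (a classification record).
#' @export
classify_intergenic <- function(lnc, partner, cfg = classifier_config()) {
  if (lnc$chrom != partner$chrom) stop("different chromosomes")
  if (!(lnc$end <= partner$start || partner$end <= lnc$start))
    stop("spans overlap; use classify_genic")
  partner_right <- partner$start >= lnc$end
  gap <- if (partner_right) partner$start - lnc$end else lnc$start - partner$end
  side <- if (lnc$strand == "-") {
    if (partner_right) "upstream" else "downstream"
  } else {
    if (partner_right) "downstream" else "upstream"
  }
  orientation <- if (lnc$strand == partner$strand) "same_strand" else {
    left_strand <- if (partner_right) lnc$strand else partner$strand
    # opposite strands: left transcript on '-' means the 5' ends meet in the
    # gap (head-to-head, divergent); left on '+' means the 3' ends meet
    if (left_strand == "-") "divergent" else "convergent"
  }
  tibble::tibble(
    lnc_transcript_id = lnc$transcript_id,
    partner_transcript_id = partner$transcript_id,
    type = "INTERGENIC", direction = side, location = orientation,
    subtype = NA_character_, distance = as.integer(gap)
  )
}

#' Classify all candidate lncRNA transcripts against a reference
#'
#' Reports every genic interaction, plus intergenic interactions within the
#' search window: partners within `window_min` bp when any exist, otherwise
#' the window expands up to `window_max` (with `strict_band`, only partners
#' with `window_min <= gap <= window_max` are reported). Exactly one best
#' partner per classified lncRNA is flagged: genic beats intergenic; among
#' genic, largest exonic overlap, then largest span overlap, then smallest
#' partner ID; among intergenic, smallest distance, then smallest ID.
#'
#' @param candidates annotation_set of (prefiltered) lncRNA transcripts.
#' @param reference annotation_set of reference transcripts (partners).
#' @param cfg classifier_config.
#' @return list with `records` (tibble of classification records incl.
#'   `is_best_partner`), `unclassified` (lncRNA transcript IDs with no
#'   partner in window), and `count_matrix` (Table-style counts over best
#'   partners: `$genic` 4 x 3 and `$intergenic` 2 x 3 matrices).
#' @export
classify_all <- function(candidates, reference, cfg = classifier_config()) {
  lt <- candidates$transcripts
  rt <- reference$transcripts
  recs <- list()
  unclassified <- character(0)
  for (i in seq_len(nrow(lt))) {
    l <- lt[i, ]
    lex <- candidates$exons[candidates$exons$transcript_id == l$transcript_id, ]
    same_chr <- rt[rt$chrom == l$chrom & rt$transcript_id != l$transcript_id, ]
    if (nrow(same_chr) == 0) { unclassified <- c(unclassified, l$transcript_id); next }
    ov <- same_chr$start < l$end & same_chr$end > l$start
    genic <- same_chr[ov, ]
    inter <- same_chr[!ov, ]
    gap <- ifelse(inter$start >= l$end, inter$start - l$end, l$start - inter$end)
    if (cfg$strict_band) {
      inter <- inter[gap >= cfg$window_min & gap <= cfg$window_max, ]
    } else {
      near <- gap <= cfg$window_min
      inter <- if (any(near)) inter[near, ] else inter[gap <= cfg$window_max, ]
    }
    ri <- list()
    for (j in seq_len(nrow(genic))) {
      p <- genic[j, ]
      pex <- reference$exons[reference$exons$transcript_id == p$transcript_id, ]
      r <- classify_genic(l, p, lex, pex)
      r$exon_overlap <- exon_overlap_bases(lex, pex)
      r$span_overlap <- min(l$end, p$end) - max(l$start, p$start)
      ri[[length(ri) + 1]] <- r
    }
    for (j in seq_len(nrow(inter))) {
      r <- classify_intergenic(l, inter[j, ], cfg)
      r$exon_overlap <- 0; r$span_overlap <- 0
      ri[[length(ri) + 1]] <- r
    }
    if (!length(ri)) { unclassified <- c(unclassified, l$transcript_id); next }
    ri <- dplyr::bind_rows(ri)
    ord <- order(ri$type != "GENIC",                      # genic first
                 -ri$exon_overlap, -ri$span_overlap,       # genic keys
                 dplyr::coalesce(ri$distance, 0L),         # intergenic key
                 ri$partner_transcript_id)
    ri$is_best_partner <- FALSE
    ri$is_best_partner[ord[1]] <- TRUE
    recs[[length(recs) + 1]] <- ri
  }
  records <- if (length(recs)) dplyr::bind_rows(recs) else
    tibble::tibble(lnc_transcript_id = character(), partner_transcript_id = character(),
                   type = character(), direction = character(), location = character(),
                   subtype = character(), distance = integer(),
                   exon_overlap = numeric(), span_overlap = numeric(),
                   is_best_partner = logical())
  list(records = records,
       unclassified = unclassified,
       count_matrix = classification_counts(records[records$is_best_partner, ]))
}

# exons within a normalized transcript are disjoint, so total overlap is the
# sum over exon pairs
exon_overlap_bases <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ov <- pmin(rep(a$end, times = nrow(b)), rep(b$end, each = nrow(a))) -
    pmax(rep(a$start, times = nrow(b)), rep(b$start, each = nrow(a)))
  sum(ov[ov > 0])
}

#' Count matrix over classification records
#'
#' @param records tibble of classification records (typically best-partner
#'   records only).
#' @return list with `genic` (4 direction-location rows x 3 subtype
#'   columns) and `intergenic` (2 side rows x 3 orientation columns)
#'   integer matrices.
#' @export
classification_counts <- function(records) {
  g <- records[records$type == "GENIC", ]
  gm <- table(
    factor(paste(g$direction, g$location),
           levels = c("antisense exonic", "antisense intronic",
                      "sense exonic", "sense intronic")),
    factor(g$subtype, levels = c("overlapping", "containing", "nested"))
  )
  i <- records[records$type == "INTERGENIC", ]
  im <- table(
    factor(i$direction, levels = c("upstream", "downstream")),
    factor(i$location, levels = c("convergent", "divergent", "same_strand"))
  )
  list(genic = unclass(gm), intergenic = unclass(im))
}

#' Write classification records and count matrices as TSV
#'
#' @param result output of [classify_all()].
#' @param records_path TSV path for the records.
#' @param counts_path TSV path for the stacked count matrix.
#' @return the two paths, invisibly.
#' @export
write_classification <- function(result, records_path, counts_path) {
  utils::write.table(result$records, records_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cm <- result$count_matrix
  block_lines <- function(block, m) {
    c(paste(c("block", "cell", colnames(m)), collapse = "\t"),
      vapply(seq_len(nrow(m)), function(i)
        paste(c(block, rownames(m)[i], m[i, ]), collapse = "\t"), character(1)))
  }
  writeLines(c(block_lines("GENIC", cm$genic),
               block_lines("INTERGENIC", cm$intergenic)), counts_path)
  invisible(c(records = records_path, counts = counts_path))
}
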
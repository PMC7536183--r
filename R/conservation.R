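## Per-exon conservation aggregation: overlapping exons are merged before
## averaging a per-base score track (phastCons/phyloP-style) so no base is
## counted twice, then summarized by biotype.

#' Score track container
#'
#' Piecewise-constant per-base scores as (chrom, start, end, score) runs,
#' 0-based half-open, sorted and non-overlapping within a chromosome.
#'
#' @param runs tibble with `chrom`, `start`, `end`, `score`.
#' @return object of class `score_track`.
#' @export
score_track <- function(runs) {
  runs <- tibble::as_tibble(runs)[, c("chrom", "start", "end", "score")]
  if (any(runs$start >= runs$end)) stop("run with start >= end")
  if (any(!is.finite(runs$score))) stop("non-finite score")
  runs <- runs[order(runs$chrom, runs$start), ]
  ov <- runs$chrom[-1] == runs$chrom[-nrow(runs)] &
    runs$start[-1] < runs$end[-nrow(runs)]
  if (nrow(runs) > 1 && any(ov)) stop("overlapping runs in score track")
  structure(list(runs = runs), class = "score_track")
}

#' Read / write a score track in BedGraph format
#'
#' BedGraph is 0-based half-open, matching the internal convention.
#'
#' @param path BedGraph file.
#' @return score_track.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  score_track(tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = as.numeric(gr$score)
  ))
}

#' @param track score_track.
#' @rdname read_bedgraph
#' @return (write) `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  r <- track$runs
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%s", r$chrom, r$start, r$end,
                     formatC(r$score, format = "g", digits = 10)),
             con = con, sep = "\n")
  invisible(path)
}

#' Merge overlapping exons of a gene
#'
#' Interval union of exon intervals, per gene (default) or within each
#' transcript, so conservation scores of overlapping base pairs are not
#' counted more than once.
#'
#' @param set annotation_set.
#' @param gene_id gene to process.
#' @param scope `"per_gene"` (default) or `"per_transcript"`.
#' @return tibble of merged exons: `chrom`, `start`, `end`, `gene_id`,
#'   `biotype` (plus `transcript_id` for per_transcript scope).
#' @export
merge_exons <- function(set, gene_id, scope = c("per_gene", "per_transcript")) {
  scope <- match.arg(scope)
  g <- set$genes[set$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) stop("unknown gene: ", gene_id)
  tx <- set$transcripts$transcript_id[set$transcripts$gene_id == gene_id]
  ex <- set$exons[set$exons$transcript_id %in% tx, ]
  if (nrow(ex) == 0) stop("gene without exons: ", gene_id)
  grp <- if (scope == "per_gene") rep(gene_id, nrow(ex)) else ex$transcript_id
  gr <- GenomicRanges::GRanges(grp, IRanges::IRanges(ex$start + 1L, ex$end))
  red <- GenomicRanges::reduce(gr)
  out <- tibble::tibble(
    chrom = g$chrom,
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    gene_id = g$gene_id,
    biotype = g$biotype
  )
  if (scope == "per_transcript") {
    out$transcript_id <- as.character(GenomicRanges::seqnames(red))
    out <- out[order(out$transcript_id, out$start), ]
  } else {
    out <- out[order(out$start), ]
  }
  out
}

#' Mean per-base score over an interval
#'
#' @param chrom,start,end interval, 0-based half-open.
#' @param track score_track.
#' @param uncovered `"ignore"` (mean over covered bases only; `NA` when the
#'   interval is fully uncovered) or `"zero"` (uncovered bases count as 0).
#' @return numeric mean, or `NA`.
#' @export
mean_score <- function(chrom, start, end, track,
                       uncovered = c("ignore", "zero")) {
  uncovered <- match.arg(uncovered)
  res <- mean_scores_bulk(tibble::tibble(chrom = chrom, start = start, end = end),
                          track, uncovered)
  res$mean_score[1]
}

# vectorized scoring of many intervals against the track
mean_scores_bulk <- function(iv, track, uncovered = "ignore") {
  r <- track$runs
  out <- rep(NA_real_, nrow(iv))
  cov <- numeric(nrow(iv)); ssum <- numeric(nrow(iv))
  if (nrow(r) > 0 && nrow(iv) > 0) {
    ig <- intervals_granges(iv$chrom, iv$start, iv$end)
    rg <- intervals_granges(r$chrom, r$start, r$end)
    # a query chromosome absent from the track is expected (rows stay NA)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(ig, rg))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (length(qi)) {
      w <- pmin(iv$end[qi], r$end[si]) - pmax(iv$start[qi], r$start[si])
      cov_by <- rowsum(w, qi)
      sum_by <- rowsum(w * r$score[si], qi)
      idx <- as.integer(rownames(cov_by))
      cov[idx] <- cov_by[, 1]
      ssum[idx] <- sum_by[, 1]
    }
  }
  len <- iv$end - iv$start
  if (uncovered == "ignore") {
    ok <- cov > 0
    out[ok] <- ssum[ok] / cov[ok]
  } else {
    out <- ssum / len
  }
  tibble::tibble(mean_score = out, covered = cov, length = len)
}

#' Per-exon conservation table with biotype summaries
#'
#' One row per merged exon of every gene in the set, with the mean
#' per-base score, plus distribution summaries (count, mean, quartiles) of
#' exon scores per biotype — the protein-coding vs lncRNA comparison view.
#'
#' @param set normalized annotation_set.
#' @param track score_track.
#' @param scope,uncovered passed to [merge_exons()] / [mean_score()].
#' @return list with `exons` (tibble gene_id, chrom, start, end, biotype,
#'   mean_score) and `summary` (tibble per biotype).
#' @export
conservation_table <- function(set, track, scope = "per_gene",
                               uncovered = "ignore") {
  rows <- lapply(set$genes$gene_id, function(g) merge_exons(set, g, scope))
  ex <- dplyr::bind_rows(rows)
  sc <- mean_scores_bulk(ex, track, uncovered)
  ex$mean_score <- sc$mean_score
  summ <- dplyr::summarise(
    dplyr::group_by(ex, .data$biotype),
    n_exons = dplyr::n(),
    n_scored = sum(!is.na(.data$mean_score)),
    mean = mean(.data$mean_score, na.rm = TRUE),
    q25 = stats::quantile(.data$mean_score, 0.25, na.rm = TRUE, names = FALSE),
    median = stats::median(.data$mean_score, na.rm = TRUE),
    q75 = stats::quantile(.data$mean_score, 0.75, na.rm = TRUE, names = FALSE),
    .groups = "drop"
  )
  list(exons = ex, summary = summ)
}

#' Write merged exons as BED6
#'
#' @param exons tibble from [merge_exons()]/[conservation_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(exons, path) {
  score <- if ("mean_score" %in% names(exons)) exons$mean_score
           else rep(NA_real_, nrow(exons))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                     exons$chrom, exons$start, exons$end, exons$gene_id,
                     ifelse(is.na(score), "0", as.character(score)), "."),
             con = con, sep = "\n")
  invisible(path)
}
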